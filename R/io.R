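#' Write and read genotype tables
#'
#' The genotype TSV has one row per marker with columns `marker`, `chrom`,
#' `pos_cm`, `pos_mb` followed by one column per line (calls 0/1/NA), plus
#' `#chrom` header comments recording the chromosome lengths so the genome
#' specification survives a round trip. Founder alleles go to a companion
#' TSV (`marker` plus one 0/1 column per founder).
#'
#' @param geno A [genotype_lines()] object.
#' @param path Output path for the genotype TSV.
#' @param founders_path Output path for the founder-allele TSV (default:
#'   `path` with a `.founders.tsv` suffix).
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(geno, path,
                               founders_path = sub("\\.tsv$", ".founders.tsv", path)) {
  spec <- geno$spec
  header <- c(
    sprintf("#scheme\t%s", geno$scheme %||% "NA"),
    sprintf("#chrom\t%d\t%.9g\t%.9g", spec$chrom, spec$length_mb, spec$length_cm)
  )
  tab <- cbind(
    geno$map[, c("marker", "chrom", "pos_cm", "pos_mb")],
    as_tibble(t(geno$calls), .name_repair = "minimal")
  )
  names(tab) <- c("marker", "chrom", "pos_cm", "pos_mb", geno$line_ids)
  writeLines(header, path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)

  ft <- cbind(tibble(marker = geno$map$marker),
              as_tibble(t(geno$founders$alleles), .name_repair = "minimal"))
  names(ft) <- c("marker", geno$founders$ids)
  readr::write_tsv(ft, founders_path)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @return `read_genotype_table()`: a list with `map`, `geno` (a
#'   `genotype_matrix`), `founders` and `spec` (NULL if the file carries no
#'   `#chrom` header).
#' @export
read_genotype_table <- function(path, founders_path = sub("\\.tsv$", ".founders.tsv", path)) {
  hdr <- readLines(path, n = 200L)
  hdr <- hdr[startsWith(hdr, "#")]
  spec <- NULL
  scheme <- NA_character_
  ch <- hdr[startsWith(hdr, "#chrom")]
  if (length(ch)) {
    parts <- do.call(rbind, strsplit(ch, "\t", fixed = TRUE))
    spec <- genome_spec(chrom_length_mb = as.numeric(parts[, 3L]),
                        chrom_length_cm = as.numeric(parts[, 4L]))
  }
  sc <- hdr[startsWith(hdr, "#scheme")]
  if (length(sc)) scheme <- strsplit(sc[1L], "\t", fixed = TRUE)[[1L]][2L]

  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         na = c("NA", ""))
  need <- c("marker", "chrom", "pos_cm", "pos_mb")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(paste0("Genotype table is missing columns: ", paste(miss, collapse = ", ")))
  }
  line_cols <- setdiff(names(tab), need)
  if (!length(line_cols)) abort("Genotype table has no line columns.")
  map <- tab[, need]
  validate_genetic_map(map, spec)

  calls <- t(as.matrix(tab[, line_cols]))
  bad <- which(!(is.na(calls) | calls == 0 | calls == 1))
  if (length(bad)) {
    rows <- sort(unique(((bad - 1L) %/% nrow(calls)) + 1L))
    abort(sprintf("Unknown call symbols (not 0/1/NA) at table row(s): %s.",
                  paste(head(rows, 5L), collapse = ", ")))
  }
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(line_cols, map$marker)

  ftab <- readr::read_tsv(founders_path, comment = "#", show_col_types = FALSE)
  if (!identical(ftab$marker, map$marker)) {
    abort("Founder table markers do not match the genotype table.")
  }
  f_ids <- setdiff(names(ftab), "marker")
  alleles <- t(as.matrix(ftab[, f_ids]))
  storage.mode(alleles) <- "integer"
  dimnames(alleles) <- list(f_ids, map$marker)
  founders <- structure(list(ids = f_ids, alleles = alleles), class = "founder_set")

  geno <- structure(
    list(calls = calls, map = map, founders = founders, spec = spec,
         scheme = scheme, line_ids = line_cols),
    class = "genotype_matrix"
  )
  list(map = map, geno = geno, founders = founders, spec = spec)
}

# positions are stored in Mb; BED-family outputs use integer base pairs
mb_to_bp <- function(x) as.integer(round(x * 1e6))

#' Write breakpoints as BED
#'
#' One record per breakpoint: the flanking-marker interval, with the line id
#' in the name column.
#'
#' @param bps A `breakpoint_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breakpoints_bed <- function(bps, path) {
  bed <- tibble(
    chrom = paste0("chr", bps$chrom),
    start = mb_to_bp(bps$left_mb),
    end = mb_to_bp(bps$right_mb),
    name = as.character(bps$line)
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write a windowed recombination-frequency track as bedGraph
#'
#' @param track A tibble from [windowed_recfreq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recfreq_bedgraph <- function(track, path) {
  bg <- tibble(
    chrom = paste0("chr", track$chrom),
    start = mb_to_bp(track$start_mb),
    end = mb_to_bp(track$end_mb),
    value = round(track$freq_cm_mb, 6)
  )
  readr::write_tsv(bg, path, col_names = FALSE)
  invisible(path)
}

#' Write a bin partition as BED
#'
#' @param bins A tibble from [build_bin_partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bins_bed <- function(bins, path) {
  bed <- tibble(
    chrom = paste0("chr", bins$chrom),
    start = mb_to_bp(bins$start_mb),
    end = mb_to_bp(bins$end_mb),
    name = sprintf("bin_%05d", seq_len(nrow(bins)))
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
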