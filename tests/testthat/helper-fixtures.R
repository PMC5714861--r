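# Shared fixtures and independent oracles, all built in code.

one_chrom_spec <- function(mb = 100, cm = 100) genome_spec(mb, cm)

# a genotype_matrix built directly from a call matrix (for unit tests)
make_geno <- function(calls, map, founders, spec = NULL, scheme = "test") {
  storage.mode(calls) <- "integer"
  structure(
    list(calls = calls, map = map, founders = founders, spec = spec,
         scheme = scheme,
         line_ids = rownames(calls) %||% sprintf("line_%03d", seq_len(nrow(calls)))),
    class = "genotype_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a founder_set with explicit alleles (rows = founders)
make_founders <- function(alleles, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("P%d", seq_len(nrow(alleles)))
  storage.mode(alleles) <- "integer"
  rownames(alleles) <- ids
  structure(list(ids = ids, alleles = alleles), class = "founder_set")
}

# simple uniform map on an arbitrary spec
uniform_map <- function(spec, n_markers) {
  build_genetic_map(spec, n_markers, placement = "uniform")
}

# Exhaustive bin-count oracle: plain loops, no smoothing, no shared code with
# the implementation. Counts distinct breakpoint midpoints per chromosome,
# pooled over lines, plus one bin per chromosome.
oracle_bin_number <- function(labels, map, spec) {
  total <- 0L
  for (ch in spec$chrom) {
    idx <- which(map$chrom == ch)
    mids <- c()
    for (i in seq_len(nrow(labels))) {
      prev_lab <- NA
      prev_pos <- NA
      for (j in idx) {
        lab <- labels[i, j]
        if (is.na(lab)) next
        if (!is.na(prev_lab) && lab != prev_lab) {
          mids <- c(mids, (prev_pos + map$pos_mb[j]) / 2)
        }
        prev_lab <- lab
        prev_pos <- map$pos_mb[j]
      }
    }
    total <- total + length(unique(mids)) + 1L
  }
  total
}

# Per-line/homolog tiling check for simulated mosaics
expect_mosaic_tiles <- function(pop) {
  segs <- tibble::as_tibble(pop)
  for (key in split(segs, interaction(segs$line, segs$homolog, segs$chrom, drop = TRUE))) {
    l <- pop$spec$length_mb[pop$spec$chrom == key$chrom[1]]
    key <- key[order(key$start_mb), ]
    expect_equal(key$start_mb[1], 0)
    expect_equal(key$end_mb[nrow(key)], l)
    if (nrow(key) > 1) {
      expect_equal(key$start_mb[-1], key$end_mb[-nrow(key)])
      expect_true(all(key$founder[-1] != key$founder[-nrow(key)]))
    }
    expect_equal(sum(key$end_mb - key$start_mb), l)
  }
}
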