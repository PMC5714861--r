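#' Describe a genome for simulation
#'
#' A genome specification is a tibble with one row per chromosome giving its
#' physical length in Mb and its genetic length in cM. It parameterises the
#' population simulator and all downstream interval bookkeeping (segment
#' tables, recombination bins, frequency windows).
#'
#' @param chrom_length_mb Numeric vector of per-chromosome physical lengths
#'   (Mb). All values must be positive.
#' @param chrom_length_cm Numeric vector of per-chromosome genetic lengths
#'   (cM), same length as `chrom_length_mb`. Values must be non-negative; a
#'   0-cM chromosome never recombines.
#' @return A tibble of class `genome_spec` with columns `chrom`, `length_mb`,
#'   `length_cm`.
#' @seealso [maize_genome_spec()] for the default maize-like genome.
#' @export
#' @examples
#' genome_spec(chrom_length_mb = c(100, 80), chrom_length_cm = c(120, 90))
genome_spec <- function(chrom_length_mb, chrom_length_cm) {
  if (length(chrom_length_mb) != length(chrom_length_cm)) {
    abort("`chrom_length_mb` and `chrom_length_cm` must have the same length.")
  }
  if (length(chrom_length_mb) < 1L) {
    abort("A genome needs at least one chromosome.")
  }
  if (any(!is.finite(chrom_length_mb)) || any(chrom_length_mb <= 0)) {
    abort("All physical chromosome lengths must be positive and finite.")
  }
  if (any(!is.finite(chrom_length_cm)) || any(chrom_length_cm < 0)) {
    abort("All genetic chromosome lengths must be non-negative and finite.")
  }
  out <- tibble(
    chrom = seq_along(chrom_length_mb),
    length_mb = as.numeric(chrom_length_mb),
    length_cm = as.numeric(chrom_length_cm)
  )
  class(out) <- c("genome_spec", class(out))
  out
}

#' Default maize-like genome specification
#'
#' Ten chromosomes with lengths in B73-like proportions, scaled to a total
#' physical size of 2,300 Mb and a total genetic length of 1,600 cM. With a
#' 1,600-cM map a single meiosis carries on average 16 crossovers, so a
#' doubled-haploid line averages 16 recombination events, matching the
#' per-line DH mean reported for SNP50-genotyped maize populations.
#'
#' @param n_chromosomes Number of chromosomes. For 10 (the default) the
#'   B73-like length proportions are used; otherwise chromosomes are equal
#'   sized.
#' @param total_mb Total genome physical length in Mb (default 2,300).
#' @param total_cm Total genome genetic length in cM (default 1,600).
#' @return A [genome_spec()] tibble.
#' @export
maize_genome_spec <- function(n_chromosomes = 10, total_mb = 2300, total_cm = 1600) {
  if (n_chromosomes == 10) {
    # B73 RefGen_v2-like relative chromosome sizes
    w <- c(301, 237, 232, 242, 218, 169, 177, 175, 157, 151)
  } else {
    w <- rep(1, n_chromosomes)
  }
  w <- w / sum(w)
  genome_spec(chrom_length_mb = w * total_mb, chrom_length_cm = w * total_cm)
}

#' Total genome lengths and chromosome count
#'
#' @param spec A [genome_spec()].
#' @return A single number.
#' @export
total_length_mb <- function(spec) sum(spec$length_mb)

#' @rdname total_length_mb
#' @export
total_length_cm <- function(spec) sum(spec$length_cm)

#' @rdname total_length_mb
#' @export
n_chromosomes <- function(spec) nrow(spec)

#' Build a genetic map of markers on a genome
#'
#' Allocates markers to chromosomes proportionally to their genetic length
#' (at least two per chromosome) and places them either uniformly or
#' uniformly at random along the physical axis. Genetic positions follow a
#' linear cM-Mb relation per chromosome, i.e. a uniform recombination
#' density; custom maps with hot or cold regions (e.g. a centromeric plateau
#' in cM) can be supplied directly as a tibble with the same columns.
#'
#' @param spec A [genome_spec()].
#' @param n_markers Total number of markers (>= 2 per chromosome).
#' @param placement `"uniform"` (equally spaced, endpoints included) or
#'   `"random"` (uniform draws on the physical axis).
#' @param seed Optional integer seed for random placement.
#' @return A tibble with columns `marker`, `chrom`, `pos_cm`, `pos_mb`,
#'   sorted by chromosome and physical position.
#' @export
#' @examples
#' spec <- genome_spec(100, 100)
#' build_genetic_map(spec, 11, placement = "uniform")
build_genetic_map <- function(spec, n_markers,
                              placement = c("uniform", "random"),
                              seed = NULL) {
  placement <- match.arg(placement)
  nc <- n_chromosomes(spec)
  if (n_markers < 2L * nc) {
    abort(sprintf("`n_markers` must be at least 2 per chromosome (>= %d).", 2L * nc))
  }
  w <- spec$length_cm
  if (sum(w) <= 0) w <- spec$length_mb
  n_chr <- allocate_proportional(n_markers, w, min_each = 2L)

  place_one <- function(i) {
    k <- n_chr[i]
    l_mb <- spec$length_mb[i]
    l_cm <- spec$length_cm[i]
    if (placement == "uniform") {
      pos_mb <- seq(0, l_mb, length.out = k)
    } else {
      pos_mb <- sort(runif(k, 0, l_mb))
      while (anyDuplicated(pos_mb) > 0L) {
        pos_mb <- sort(runif(k, 0, l_mb))
      }
    }
    tibble(
      marker = sprintf("c%02dm%05d", i, seq_len(k)),
      chrom = spec$chrom[i],
      pos_cm = pos_mb * (if (l_mb > 0) l_cm / l_mb else 0),
      pos_mb = pos_mb
    )
  }

  build <- function() list_rbind(map(seq_len(nc), place_one))
  if (placement == "random" && !is.null(seed)) {
    withr::with_seed(seed, build())
  } else {
    build()
  }
}

# Largest-remainder allocation of n items to weights, with a floor per cell.
allocate_proportional <- function(n, w, min_each = 2L) {
  k <- length(w)
  base <- rep(min_each, k)
  rest <- n - sum(base)
  if (rest > 0) {
    share <- rest * w / sum(w)
    extra <- floor(share)
    rem <- rest - sum(extra)
    if (rem > 0) {
      ord <- order(share - extra, decreasing = TRUE)
      extra[ord[seq_len(rem)]] <- extra[ord[seq_len(rem)]] + 1L
    }
    base <- base + as.integer(extra)
  }
  base
}

#' Validate a genetic map against a genome specification
#'
#' Checks column presence, per-chromosome sorting, the no-duplicate rule for
#' physical positions, and that positions fall inside the chromosome.
#'
#' @param map A genetic-map tibble (`marker`, `chrom`, `pos_cm`, `pos_mb`).
#' @param spec Optional [genome_spec()] to check positions against.
#' @return The map, invisibly; aborts with an informative message otherwise.
#' @export
validate_genetic_map <- function(map, spec = NULL) {
  need <- c("marker", "chrom", "pos_cm", "pos_mb")
  miss <- setdiff(need, names(map))
  if (length(miss)) abort(paste0("Map is missing columns: ", paste(miss, collapse = ", ")))
  for (ch in unique(map$chrom)) {
    m <- map[map$chrom == ch, ]
    if (is.unsorted(m$pos_mb, strictly = TRUE)) {
      dup <- m$marker[duplicated(m$pos_mb)]
      if (length(dup)) {
        abort(sprintf("Duplicated physical position on chromosome %s at marker %s.",
                      ch, dup[1]))
      }
      abort(sprintf("Markers on chromosome %s are not sorted by physical position.", ch))
    }
    if (is.unsorted(m$pos_cm)) {
      abort(sprintf("Genetic positions on chromosome %s are not nondecreasing.", ch))
    }
    if (!is.null(spec)) {
      l_mb <- spec$length_mb[spec$chrom == ch]
      l_cm <- spec$length_cm[spec$chrom == ch]
      if (any(m$pos_mb < 0) || any(m$pos_mb > l_mb + 1e-9)) {
        abort(sprintf("Physical positions outside [0, %g] on chromosome %s.", l_mb, ch))
      }
      if (any(m$pos_cm < 0) || any(m$pos_cm > l_cm + 1e-9)) {
        abort(sprintf("Genetic positions outside [0, %g] on chromosome %s.", l_cm, ch))
      }
    }
  }
  invisible(map)
}
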