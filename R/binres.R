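#' Build the pooled recombination-bin partition of a line set
#'
#' A recombination bin is a chromosomal segment devoid of recombination
#' across the chosen lines: pooling every line's breakpoints and cutting each
#' chromosome at the distinct boundaries yields the bin partition.
#' Breakpoints are resolved to flanking-marker intervals, so two lines
#' recombining within the same marker interval share one boundary (the
#' interval midpoint) — the finest partition computable at chip resolution.
#'
#' @param bps A `breakpoint_set`.
#' @param spec The [genome_spec()].
#' @param lines Optional character vector restricting to a line subset.
#' @return A tibble of bins: `chrom`, `start_mb`, `end_mb`, `length_mb`.
#'   Bin number is `nrow()`; see [bin_number()] and [mean_bin_size()].
#' @export
build_bin_partition <- function(bps, spec, lines = NULL) {
  if (!is.null(lines)) {
    if (!length(lines)) abort("`lines` must name at least one line.")
    bps <- bps[as.character(bps$line) %in% lines, ]
  } else if (!length(levels(bps$line))) {
    abort("The breakpoint set contains no lines.")
  }
  out <- vector("list", nrow(spec))
  for (ci in seq_len(nrow(spec))) {
    l <- spec$length_mb[ci]
    cuts <- sort(unique(bps$pos_mb[bps$chrom == spec$chrom[ci]]))
    cuts <- cuts[cuts > 0 & cuts < l]
    b <- c(0, cuts, l)
    out[[ci]] <- tibble(chrom = spec$chrom[ci], start_mb = b[-length(b)],
                        end_mb = b[-1L], length_mb = diff(b))
  }
  list_rbind(out)
}

#' Bin-partition summary statistics
#'
#' @param bins A bin partition from [build_bin_partition()].
#' @return `bin_number()`: the number of bins; `mean_bin_size()`: total
#'   genome length divided by the bin number, in Mb.
#' @export
bin_number <- function(bins) nrow(bins)

#' @rdname bin_number
#' @export
mean_bin_size <- function(bins) sum(bins$length_mb) / nrow(bins)

#' Recombination-bin statistics under line and marker subsampling
#'
#' For every cell of the `line_counts` x `marker_counts` grid, draws `R`
#' independent subsets of lines and of markers (both without replacement,
#' markers uniformly genome-wide and redrawn every resample), recomputes
#' origin labels restricted to the marker subset, detects breakpoints, and
#' records the bin number and mean bin size of the pooled partition. Mean
#' and standard deviation over the `R` resamples are returned per cell.
#'
#' @param origin An `origin_matrix` for the full population and marker set.
#' @param spec The [genome_spec()].
#' @param line_counts Line subset sizes (default the usual 50/100/150/200).
#' @param marker_counts Marker subset sizes.
#' @param R Resamples per cell (default 1000).
#' @param smooth Singleton smoothing for breakpoint detection.
#' @param seed Integer seed; the full grid is reproducible from it.
#' @return A tidy tibble: `scheme`, `n_lines`, `n_markers`, `stat`
#'   (`"bin_number"` or `"mean_bin_size_mb"`), `mean`, `sd`, `R`.
#' @export
resample_bins <- function(origin, spec, line_counts = c(50, 100, 150, 200),
                          marker_counts = c(200, 500, 1000, 2000, 5000, 7500, 10000),
                          R = 1000, smooth = TRUE, seed = 1L) {
  lab <- origin$origin
  n <- nrow(lab)
  m <- ncol(lab)
  bad_l <- line_counts[line_counts > n]
  if (length(bad_l)) {
    abort(sprintf("Requested line counts exceed the %d available lines: %s.",
                  n, paste(bad_l, collapse = ", ")))
  }
  bad_m <- marker_counts[marker_counts > m]
  if (length(bad_m)) {
    abort(sprintf("Requested marker counts exceed the %d available markers: %s.",
                  m, paste(bad_m, collapse = ", ")))
  }
  chrom_of <- origin$map$chrom
  pos_mb <- origin$map$pos_mb
  total_mb <- total_length_mb(spec)
  nchr <- nrow(spec)

  grid <- expand.grid(n_lines = line_counts, n_markers = marker_counts,
                      KEEP.OUT.ATTRS = FALSE)
  res <- withr::with_seed(seed, {
    cells <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) {
      nl <- grid$n_lines[g]
      nm <- grid$n_markers[g]
      bn <- numeric(R)
      for (r in seq_len(R)) {
        li <- sample.int(n, nl)
        mi <- sort(sample.int(m, nm))
        bn[r] <- pooled_bin_number(lab, li, mi, chrom_of, pos_mb, nchr, smooth)
      }
      bs <- total_mb / bn
      cells[[g]] <- tibble(
        n_lines = nl, n_markers = nm,
        stat = c("bin_number", "mean_bin_size_mb"),
        mean = c(mean(bn), mean(bs)),
        sd = c(sd(bn), sd(bs)),
        R = R
      )
    }
    list_rbind(cells)
  })
  res$scheme <- origin$scheme %||% NA_character_
  res[, c("scheme", "n_lines", "n_markers", "stat", "mean", "sd", "R")]
}

# Pooled bin count of a (line, marker) subset: distinct boundary midpoints
# per chromosome + one bin per chromosome (bins tile the whole genome, so
# every chromosome contributes at least one bin even without markers).
pooled_bin_number <- function(lab, li, mi, chrom_of, pos_mb, nchr, smooth) {
  sub <- lab[li, mi, drop = FALSE]
  per_chrom <- split(seq_along(mi), chrom_of[mi])
  n <- length(li)
  total <- nchr
  for (cols in per_chrom) {
    if (length(cols) < 2L) next
    pos <- pos_mb[mi[cols]]
    mids <- vector("list", n)
    for (i in seq_len(n)) {
      chg <- label_changes(sub[i, cols], smooth)
      if (!is.null(chg)) {
        mids[[i]] <- (pos[chg[[1L]]] + pos[chg[[2L]]]) / 2
      }
    }
    total <- total + length(unique(unlist(mids, use.names = FALSE)))
  }
  total
}

# Indices (left, right) of informative-marker label changes along one
# chromosome's label vector, after optional singleton smoothing.
label_changes <- function(v, smooth) {
  known <- which(!is.na(v))
  if (length(known) < 2L) return(NULL)
  vv <- v[known]
  if (smooth && length(known) >= 3L) {
    kk <- length(vv)
    single <- c(FALSE, vv[2:(kk - 1)] != vv[1:(kk - 2)] &
                  vv[2:(kk - 1)] != vv[3:kk] &
                  vv[1:(kk - 2)] == vv[3:kk], FALSE)
    if (any(single)) {
      known <- known[!single]
      vv <- vv[!single]
      if (length(known) < 2L) return(NULL)
    }
  }
  chg <- which(vv[-1L] != vv[-length(vv)])
  if (!length(chg)) return(NULL)
  list(known[chg], known[chg + 1L])
}
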