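#' Simulate null (or planted-QTL) phenotypes
#'
#' `simulate_null_phenotypes()` draws independent standard-normal phenotype
#' values for every line and trait — the null model used to measure map
#' resolution. `simulate_qtl_phenotypes()` plants a single additive QTL: the
#' phenotype is `beta * code + e`, `e ~ N(0,1)`, with `beta` chosen so the
#' QTL explains a fraction `h2` of the phenotypic variance in expectation.
#'
#' @param n_lines,n_traits Dimensions of the phenotype matrix.
#' @param seed Integer seed.
#' @return A numeric matrix, lines x traits.
#' @export
simulate_null_phenotypes <- function(n_lines, n_traits, seed = 1L) {
  if (n_lines < 1 || n_traits < 1) abort("`n_lines` and `n_traits` must be >= 1.")
  withr::with_seed(seed, {
    matrix(rnorm(n_lines * n_traits), n_lines, n_traits,
           dimnames = list(NULL, sprintf("trait_%04d", seq_len(n_traits))))
  })
}

#' @rdname simulate_null_phenotypes
#' @param code Numeric genotype code of the causal marker, one value per line
#'   (e.g. a column of an origin matrix minus 1).
#' @param h2 Fraction of phenotypic variance explained by the planted QTL.
#' @export
simulate_qtl_phenotypes <- function(code, n_traits, h2 = 0.5, seed = 1L) {
  if (h2 <= 0 || h2 >= 1) abort("`h2` must lie in (0, 1).")
  s <- sd(code)
  if (!is.finite(s) || s == 0) abort("The causal-marker code has zero variance.")
  beta <- sqrt(h2 / (1 - h2)) / s
  y <- withr::with_seed(seed, {
    matrix(rnorm(length(code) * n_traits), length(code), n_traits)
  })
  y <- y + beta * code
  colnames(y) <- sprintf("trait_%04d", seq_len(n_traits))
  attr(y, "beta") <- beta
  y
}

# LOD matrix (markers x traits) for a biparental origin-code scan.
# LOD = (n/2) log10(RSS0/RSS1) from single-locus regression on the 0/1
# origin code, computed over the lines with known origin at each marker.
lod_matrix_biparental <- function(origin, Y, cap = 300) {
  X <- origin$origin - 1
  M <- !is.na(X)
  X0 <- X
  X0[!M] <- 0
  Mn <- matrix(as.numeric(M), nrow(M))
  n_m <- colSums(Mn)
  Sx <- colSums(X0)
  Sxx <- colSums(X0 * X0)
  Sy <- crossprod(Mn, Y)            # markers x traits
  Syy <- crossprod(Mn, Y * Y)
  Sxy <- crossprod(X0, Y)
  rss0 <- Syy - Sy^2 / n_m
  varx <- Sxx - Sx^2 / n_m
  cov <- Sxy - (Sx / n_m) * Sy
  adj <- cov^2 / pmax(varx, 1e-12)   # vector over markers recycles by column
  adj[varx <= 1e-12, ] <- 0
  rss1 <- rss0 - adj
  lod <- (n_m / 2) * log10(pmax(rss0, 1e-300) / pmax(rss1, 1e-300))
  lod[!is.finite(lod) | lod < 0] <- 0
  pmin(lod, cap)
}

# LOD matrix for a multi-founder scan: per marker, regression of the
# phenotype on the founder posterior probabilities (intercept absorbed by
# centring), LOD from the same RSS ratio.
lod_matrix_posterior <- function(origin, Y, cap = 300) {
  post <- origin$posteriors
  if (is.null(post)) {
    abort("Multi-founder scans need HMM posteriors; rerun infer_founder_mosaic_hmm(keep_posteriors = TRUE).")
  }
  n <- dim(post)[1L]
  m <- dim(post)[2L]
  Yc <- sweep(Y, 2L, colMeans(Y))
  rss0 <- colSums(Yc^2)
  lod <- matrix(0, m, ncol(Y))
  for (j in seq_len(m)) {
    A <- post[, j, ]
    A <- sweep(A, 2L, colMeans(A))
    qrA <- qr(A)
    r <- qrA$rank
    if (r < 1L) next
    Q <- qr.Q(qrA)[, seq_len(r), drop = FALSE]
    B <- crossprod(Q, Yc)
    rss1 <- pmax(rss0 - colSums(B^2), 1e-300)
    lod[j, ] <- pmin(pmax((n / 2) * log10(rss0 / rss1), 0), cap)
  }
  colnames(lod) <- colnames(Y)
  lod
}

lod_matrix <- function(origin, Y, cap = 300) {
  if (length(origin$founder_ids) == 2L) {
    lod_matrix_biparental(origin, Y, cap)
  } else {
    lod_matrix_posterior(origin, Y, cap)
  }
}

#' Genome scan: LOD profile of one or more phenotypes
#'
#' Single-locus regression scan. For biparental populations the phenotype is
#' regressed on the 0/1 parental-origin code at each marker (lines with
#' unknown origin at a marker are dropped there). For multi-founder
#' populations the phenotype is regressed on the founder posterior
#' probabilities from [infer_founder_mosaic_hmm()]. In both cases
#' `LOD = (N/2) log10(RSS0 / RSS1)`, capped at `cap` (perfect fits would
#' otherwise be infinite) and floored at 0.
#'
#' @param origin An `origin_matrix` (with posteriors for multi-founder data).
#' @param phenos A numeric vector (one trait) or lines x traits matrix.
#' @param cap Maximum reported LOD (default 300).
#' @return A tibble: `trait`, `marker`, `chrom`, `pos_cm`, `pos_mb`, `lod`.
#' @export
scan_lod <- function(origin, phenos, cap = 300) {
  Y <- if (is.matrix(phenos)) phenos else matrix(phenos, ncol = 1L,
                                                 dimnames = list(NULL, "trait_0001"))
  if (nrow(Y) != nrow(origin$origin)) {
    abort("Phenotype rows must match the number of lines.")
  }
  if (nrow(Y) < 10L) abort("Need at least 10 lines for a scan.")
  v <- apply(Y, 2L, var)
  if (any(!is.finite(v)) || any(v <= 0)) abort("Phenotypes must have positive variance.")
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("trait_%04d", seq_len(ncol(Y)))
  lod <- lod_matrix(origin, Y, cap)
  map <- origin$map
  out <- tibble(
    trait = rep(colnames(Y), each = nrow(map)),
    marker = rep(map$marker, ncol(Y)),
    chrom = rep(map$chrom, ncol(Y)),
    pos_cm = rep(map$pos_cm, ncol(Y)),
    pos_mb = rep(map$pos_mb, ncol(Y)),
    lod = as.numeric(lod)
  )
  out
}

# QTL calls for one trait from vectors of chrom/pos/lod: per chromosome the
# maximum-LOD position above `threshold` is one QTL; the support interval
# extends to the nearest flanking positions where LOD falls `drop` below the
# peak, linearly interpolated between markers and truncated at the terminal
# marker positions.
call_qtl_vec <- function(chrom, pos_mb, lod, threshold, drop) {
  rows <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    l <- lod[sel]
    p <- pos_mb[sel]
    pk <- which.max(l)
    if (l[pk] <= threshold) next
    target <- l[pk] - drop
    # left boundary
    left <- p[1L]
    if (pk > 1L) {
      below <- which(l[seq_len(pk - 1L)] <= target)
      if (length(below)) {
        j <- max(below)
        t <- (target - l[j]) / (l[j + 1L] - l[j])
        left <- p[j] + t * (p[j + 1L] - p[j])
      }
    }
    # right boundary
    right <- p[length(p)]
    if (pk < length(l)) {
      below <- which(l[(pk + 1L):length(l)] <= target) + pk
      if (length(below)) {
        j <- min(below)
        t <- (l[j - 1L] - target) / (l[j - 1L] - l[j])
        right <- p[j - 1L] + t * (p[j] - p[j - 1L])
      }
    }
    rows[[length(rows) + 1L]] <- tibble(
      chrom = ch, peak_mb = p[pk], peak_lod = l[pk],
      start_mb = left, end_mb = right, length_mb = right - left
    )
  }
  list_rbind(rows)
}

#' Call QTL from a LOD profile with 2-LOD support intervals
#'
#' One QTL per chromosome per trait: the maximum-LOD position, reported only
#' if it exceeds `threshold`. The support interval runs from the peak to the
#' nearest flanking positions where the LOD falls `drop` units below the
#' peak (linear interpolation between markers), truncated at the terminal
#' marker positions of the chromosome.
#'
#' @param profile A tibble from [scan_lod()].
#' @param threshold LOD significance threshold (> 0).
#' @param drop LOD decline defining the support interval (default 2).
#' @return A tibble: `trait`, `chrom`, `peak_mb`, `peak_lod`, `start_mb`,
#'   `end_mb`, `length_mb`. Zero rows when nothing exceeds the threshold.
#' @export
call_qtl <- function(profile, threshold = 3, drop = 2) {
  if (threshold <= 0) abort("`threshold` must be positive.")
  empty <- tibble(trait = character(), chrom = integer(), peak_mb = numeric(),
                  peak_lod = numeric(), start_mb = numeric(), end_mb = numeric(),
                  length_mb = numeric())
  out <- vector("list", 0L)
  for (tr in unique(profile$trait)) {
    sub <- profile[profile$trait == tr, ]
    calls <- call_qtl_vec(sub$chrom, sub$pos_mb, sub$lod, threshold, drop)
    if (!is.null(calls) && nrow(calls)) {
      calls$trait <- tr
      out[[length(out) + 1L]] <- calls[, c("trait", "chrom", "peak_mb", "peak_lod",
                                           "start_mb", "end_mb", "length_mb")]
    }
  }
  if (!length(out)) empty else list_rbind(out)
}

#' Null-phenotype map-resolution experiment across population types
#'
#' For each population: subsample `n_lines` lines, genotype them, assign
#' origins (direct matching for two founders, the founder HMM otherwise),
#' scan `n_traits` independent standard-normal phenotypes, and call QTL with
#' 2-LOD support intervals. Biparental populations use a fixed LOD threshold
#' (default 3); multi-founder populations use a data-driven cutoff placed so
#' that a fixed fraction of traits (default 37%) exceeds it genome-wide,
#' because the multi-founder regression has more degrees of freedom and a
#' fixed biparental cutoff is not comparable. The support-interval length
#' distribution is the map resolution readout.
#'
#' @param pops Named list of [simulate_population()] objects (names are used
#'   as population labels).
#' @param n_traits Number of null traits per population (default 1000).
#' @param n_lines Lines used per population (default 200).
#' @param threshold Fixed LOD threshold for biparental populations.
#' @param drop LOD decline for support intervals.
#' @param magic_trait_fraction Fraction (0-1) of traits admitted by the
#'   multi-founder cutoff: the threshold is the `1 - magic_trait_fraction`
#'   quantile of the per-trait genome-wide maximum LOD.
#' @param missing_rate,error_rate Genotyping noise injected before origin
#'   assignment.
#' @param hmm_error_rate Error rate assumed by the founder HMM.
#' @param seed Integer seed (controls subsampling, genotyping noise and the
#'   phenotype draws).
#' @return A tibble with one row per population: `population`, `n_traits`,
#'   `threshold`, `n_qtl`, `mean_interval_mb`, `sd_interval_mb`,
#'   `min_interval_mb`, `max_interval_mb`. The full call table is attached
#'   as attribute `"calls"`.
#' @export
map_resolution_experiment <- function(pops, n_traits = 1000, n_lines = 200,
                                      threshold = 3, drop = 2,
                                      magic_trait_fraction = 0.37,
                                      missing_rate = 0, error_rate = 0,
                                      hmm_error_rate = 0.01, seed = 1L) {
  if (is.null(names(pops)) || any(!nzchar(names(pops)))) {
    abort("`pops` must be a named list of populations.")
  }
  seeds <- withr::with_seed(seed, sample.int(1e8, 3L * length(pops)))
  rows <- vector("list", length(pops))
  all_calls <- vector("list", length(pops))
  for (i in seq_along(pops)) {
    pop <- pops[[i]]
    tag <- names(pops)[i]
    if (pop$n_lines < n_lines) {
      abort(sprintf("Population '%s' has %d lines; %d requested.", tag, pop$n_lines, n_lines))
    }
    sub_pop <- if (pop$n_lines > n_lines) {
      idx <- withr::with_seed(seeds[3L * i - 2L], sort(sample.int(pop$n_lines, n_lines)))
      subset_population(pop, idx)
    } else {
      pop
    }
    geno <- genotype_lines(sub_pop, missing_rate, error_rate, seed = seeds[3L * i - 1L])
    origin <- if (n_founders(pop$founders) == 2L) {
      assign_parental_origin(geno)
    } else {
      infer_founder_mosaic_hmm(geno, error_rate = hmm_error_rate)
    }
    Y <- simulate_null_phenotypes(n_lines, n_traits, seed = seeds[3L * i])
    lod <- lod_matrix(origin, Y)
    thr <- if (n_founders(pop$founders) == 2L) {
      threshold
    } else {
      unname(quantile(apply(lod, 2L, max), 1 - magic_trait_fraction))
    }
    map <- origin$map
    calls <- vector("list", ncol(Y))
    for (tr in seq_len(ncol(Y))) {
      cc <- call_qtl_vec(map$chrom, map$pos_mb, lod[, tr], thr, drop)
      if (!is.null(cc) && nrow(cc)) {
        cc$trait <- colnames(Y)[tr]
        calls[[tr]] <- cc
      }
    }
    calls <- list_rbind(calls)
    n_qtl <- if (is.null(calls)) 0L else nrow(calls)
    iv <- if (n_qtl > 0) calls$length_mb else numeric(0)
    rows[[i]] <- tibble(
      population = tag, n_traits = n_traits, threshold = thr, n_qtl = n_qtl,
      mean_interval_mb = if (n_qtl) mean(iv) else NA_real_,
      sd_interval_mb = if (n_qtl > 1) sd(iv) else NA_real_,
      min_interval_mb = if (n_qtl) min(iv) else NA_real_,
      max_interval_mb = if (n_qtl) max(iv) else NA_real_
    )
    if (n_qtl > 0) {
      calls$population <- tag
      all_calls[[i]] <- calls
    }
  }
  out <- list_rbind(rows)
  attr(out, "calls") <- list_rbind(all_calls)
  out
}

# Restrict a simulated population to a subset of line indices.
subset_population <- function(pop, idx) {
  pop$lines <- pop$lines[idx]
  pop$line_ids <- pop$line_ids[idx]
  pop$n_lines <- length(idx)
  pop
}
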