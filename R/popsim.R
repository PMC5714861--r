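#' Simulate one gamete from a parental line
#'
#' Meiosis under the Haldane model: per chromosome the crossover count is
#' Poisson with mean L/100 (L the genetic length in cM, i.e. one crossover
#' per Morgan, no interference, no obligate chiasma), crossover positions are
#' uniform on the genetic scale and mapped to physical coordinates by
#' piecewise-linear interpolation of the marker map, and the gamete
#' alternates between the two parental homologs starting from either with
#' probability 1/2. Uses the current RNG state; seed with [set.seed()] or
#' [withr::with_seed()] for reproducibility.
#'
#' @param parent A line as stored in a [simulate_population()] object
#'   (`list(h1 =, h2 =)` of per-chromosome mosaics).
#' @param map Genetic map tibble.
#' @param spec The [genome_spec()].
#' @return A single-homolog genome: a list of per-chromosome mosaics, each
#'   `list(b, f)` with segment boundaries (Mb) and founder codes.
#' @export
simulate_gamete <- function(parent, map, spec) {
  ctx <- make_meiosis_ctx(map, spec)
  gamete_genome(parent, ctx)
}

#' Simulate a mapping population under a crossing scheme
#'
#' Implements the four designs on top of the same meiosis model:
#' * **dh** — one F1 gamete doubled into a fully homozygous line.
#' * **ril** — F1 followed by `ril_selfings` generations of selfing
#'   (default 6, i.e. F7 lines).
#' * **ibm** — F2 individuals intermated to F3, F3 individuals random-mated
#'   to F4, then two generations of selfing to F6.
#' * **magic** — eight founders split into two sub-groups of four
#'   (membership randomised per line unless `params$funnel` gives a fixed
#'   founder order); pairwise F1s within each sub-group, F2 = cross of the
#'   two F1s of a sub-group, F3 = cross of F2s from different sub-groups,
#'   then `magic_selfings` generations of selfing (default 3, i.e. F6).
#'
#' Every line is an independent pedigree realisation. All randomness flows
#' through `seed`, so identical arguments give byte-identical populations.
#'
#' @param scheme One of `"dh"`, `"ril"`, `"ibm"`, `"magic"`.
#' @param founders A [founder_set()]; 2 founders for dh/ril/ibm, 8 for magic.
#' @param map Genetic map tibble.
#' @param spec The [genome_spec()].
#' @param n_lines Number of lines to simulate (>= 1).
#' @param params Optional list: `ril_selfings` (default 6), `magic_selfings`
#'   (default 3), `funnel` (integer permutation of 1:8 fixing the MAGIC
#'   funnel for all lines).
#' @param seed Integer seed.
#' @return An object of class `sim_population`.
#' @export
simulate_population <- function(scheme = c("dh", "ril", "ibm", "magic"),
                                founders, map, spec, n_lines,
                                params = list(), seed = 1L) {
  scheme <- match.arg(scheme)
  if (n_lines < 1) abort("`n_lines` must be at least 1.")
  k <- n_founders(founders)
  need <- if (scheme == "magic") 8L else 2L
  if (k != need) {
    abort(sprintf("Scheme '%s' needs %d founders, got %d.", scheme, need, k))
  }
  defaults <- list(ril_selfings = 6L, magic_selfings = 3L, funnel = NULL)
  params <- modifyList(defaults, params)
  ctx <- make_meiosis_ctx(map, spec)

  sim_line <- switch(scheme,
    dh = function() {
      f1 <- list(h1 = founder_genome(1L, spec), h2 = founder_genome(2L, spec))
      g <- gamete_genome(f1, ctx)
      list(h1 = g, h2 = g)
    },
    ril = function() {
      ind <- list(h1 = founder_genome(1L, spec), h2 = founder_genome(2L, spec))
      for (i in seq_len(params$ril_selfings)) ind <- self_line(ind, ctx)
      ind
    },
    ibm = function() {
      f1 <- list(h1 = founder_genome(1L, spec), h2 = founder_genome(2L, spec))
      f2 <- lapply(1:4, function(i) self_line(f1, ctx))
      f3a <- cross_lines(f2[[1]], f2[[2]], ctx)
      f3b <- cross_lines(f2[[3]], f2[[4]], ctx)
      ind <- cross_lines(f3a, f3b, ctx)       # F4
      for (i in 1:2) ind <- self_line(ind, ctx)  # F5, F6
      ind
    },
    magic = function() {
      perm <- if (!is.null(params$funnel)) as.integer(params$funnel) else sample.int(8L)
      f1 <- lapply(list(perm[1:2], perm[3:4], perm[5:6], perm[7:8]), function(p) {
        list(h1 = founder_genome(p[1], spec), h2 = founder_genome(p[2], spec))
      })
      f2a <- cross_lines(f1[[1]], f1[[2]], ctx)
      f2b <- cross_lines(f1[[3]], f1[[4]], ctx)
      ind <- cross_lines(f2a, f2b, ctx)       # F3
      for (i in seq_len(params$magic_selfings)) ind <- self_line(ind, ctx)
      ind
    }
  )

  lines <- withr::with_seed(seed, lapply(seq_len(n_lines), function(i) sim_line()))
  structure(
    list(scheme = scheme, lines = lines, founders = founders, map = map,
         spec = spec, seed = seed, params = params, n_lines = n_lines,
         line_ids = sprintf("%s_%04d", scheme, seq_len(n_lines))),
    class = "sim_population"
  )
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> scheme=%s, %d lines, %d founders, %d markers, seed=%s\n",
              x$scheme, x$n_lines, n_founders(x$founders), nrow(x$map), x$seed))
  invisible(x)
}

#' Tidy the haplotype mosaics of a simulated population
#'
#' @param x A `sim_population`.
#' @param ... Unused.
#' @return A tibble with one row per mosaic segment: `line`, `homolog`,
#'   `chrom`, `start_mb`, `end_mb`, `founder`.
#' @export
as_tibble.sim_population <- function(x, ...) {
  ids <- x$founders$ids
  rows <- imap(x$lines, function(ln, i) {
    per_hom <- function(h, tag) {
      list_rbind(imap(h, function(hc, ci) {
        tibble(line = x$line_ids[i], homolog = tag, chrom = x$spec$chrom[ci],
               start_mb = hc$b[-length(hc$b)], end_mb = hc$b[-1L],
               founder = ids[hc$f])
      }))
    }
    bind_rows(per_hom(ln$h1, 1L), per_hom(ln$h2, 2L))
  })
  list_rbind(rows)
}

#' True per-line recombination event counts of a simulated population
#'
#' Counts founder switches along each line's homozygous consensus (both
#' homologs carrying the same founder), the ground truth that marker-based
#' breakpoint detection estimates. Heterozygous stretches are skipped and
#' never create events, matching the unknown-skipping detection rule.
#'
#' @param pop A `sim_population`.
#' @return A tibble with columns `line`, `events`.
#' @export
true_event_counts <- function(pop) {
  tibble(
    line = pop$line_ids,
    events = vapply(pop$lines, count_consensus_junctions, integer(1))
  )
}

#' Genotype the lines of a simulated population at the map markers
#'
#' Projects each line's mosaic onto founder alleles at every marker. Markers
#' where the two homologs carry different alleles (residual heterozygosity)
#' are coded `NA`. Genotyping error then flips each non-missing call with
#' probability `error_rate`, and calls are masked to `NA` with probability
#' `missing_rate`, independently.
#'
#' @param pop A `sim_population`.
#' @param missing_rate,error_rate Per-call probabilities, each in
#'   `[0, max_rate]`.
#' @param max_rate Upper policy bound on the rates (default 0.05, the usual
#'   chip QC threshold); raise explicitly to simulate pathological data.
#' @param seed Integer seed for the noise injection.
#' @return An object of class `genotype_matrix`: a list with the integer
#'   `calls` matrix (lines x markers, values 0/1/NA), `map`, `founders`,
#'   `spec`, `scheme` and `line_ids`.
#' @export
genotype_lines <- function(pop, missing_rate = 0, error_rate = 0,
                           max_rate = 0.05, seed = 1L) {
  for (r in c(missing_rate, error_rate)) {
    if (!is.finite(r) || r < 0 || r > 1) abort("Rates must lie in [0, 1].")
  }
  if (missing_rate > max_rate || error_rate > max_rate) {
    abort(sprintf("Rates above the policy bound %g; raise `max_rate` to override.", max_rate))
  }
  map <- pop$map
  alleles <- pop$founders$alleles
  n <- pop$n_lines
  m <- nrow(map)
  chrom_idx <- split(seq_len(m), factor(map$chrom, levels = pop$spec$chrom))

  calls <- matrix(NA_integer_, n, m, dimnames = list(pop$line_ids, map$marker))
  for (i in seq_len(n)) {
    ln <- pop$lines[[i]]
    for (ci in seq_along(chrom_idx)) {
      idx <- chrom_idx[[ci]]
      if (!length(idx)) next
      pos <- map$pos_mb[idx]
      f1 <- founder_at(ln$h1[[ci]], pos)
      f2 <- founder_at(ln$h2[[ci]], pos)
      a1 <- alleles[cbind(f1, idx)]
      a2 <- alleles[cbind(f2, idx)]
      v <- ifelse(a1 == a2, a1, NA_integer_)
      calls[i, idx] <- v
    }
  }

  if (missing_rate > 0 || error_rate > 0) {
    calls <- withr::with_seed(seed, {
      obs <- !is.na(calls)
      if (error_rate > 0) {
        flip <- obs & matrix(runif(length(calls)) < error_rate, nrow(calls))
        calls[flip] <- 1L - calls[flip]
      }
      if (missing_rate > 0) {
        mask <- matrix(runif(length(calls)) < missing_rate, nrow(calls))
        calls[mask] <- NA_integer_
      }
      calls
    })
  }

  structure(
    list(calls = calls, map = map, founders = pop$founders, spec = pop$spec,
         scheme = pop$scheme, line_ids = pop$line_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d lines x %d markers (%s), %.2f%% missing\n",
              nrow(x$calls), ncol(x$calls), x$scheme,
              100 * mean(is.na(x$calls))))
  invisible(x)
}
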