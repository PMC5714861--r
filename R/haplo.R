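#' Assign parental origin at markers for a biparental population
#'
#' Direct allele matching: each non-missing call is labelled with the founder
#' carrying that allele. Missing calls, and markers where the two founders do
#' not differ, become unknown (`NA`); unknown markers are simply skipped by
#' downstream breakpoint detection and never create events.
#'
#' @param geno A [genotype_lines()] object (or an equivalent list with
#'   `calls`, `map`, `founders`).
#' @return An object of class `origin_matrix`: integer founder indices
#'   (1 or 2, `NA` unknown), lines x markers, with `provenance = "direct"`.
#' @export
assign_parental_origin <- function(geno) {
  if (n_founders(geno$founders) != 2L) {
    abort("Direct origin assignment needs exactly 2 founders; use infer_founder_mosaic_hmm().")
  }
  a <- geno$founders$alleles
  calls <- geno$calls
  lab <- matrix(NA_integer_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  m1 <- sweep(calls, 2L, a[1L, ], "==")
  m2 <- sweep(calls, 2L, a[2L, ], "==")
  lab[which(m1)] <- 1L
  lab[which(m2)] <- 2L
  lab[, a[1L, ] == a[2L, ]] <- NA_integer_
  new_origin_matrix(lab, geno, provenance = "direct")
}

#' Construct an origin matrix from precomputed labels
#'
#' Wraps a lines x markers matrix of founder labels (character labels
#' matching `founder_ids`, or integer founder indices; `NA` = unknown) so it
#' can flow into [detect_breakpoints()], [resample_bins()] and [scan_lod()].
#' Useful for importing origin calls made outside the package.
#'
#' @param labels Lines x markers matrix of founder labels or indices.
#' @param map Genetic map tibble matching the marker columns.
#' @param founder_ids Character vector of founder names.
#' @param spec Optional [genome_spec()].
#' @param scheme Optional population tag.
#' @param line_ids Line identifiers (default: rownames or `line_<i>`).
#' @param provenance Label provenance tag (default `"direct"`).
#' @return An `origin_matrix`.
#' @export
origin_matrix <- function(labels, map, founder_ids, spec = NULL, scheme = NULL,
                          line_ids = NULL, provenance = "direct") {
  if (ncol(labels) != nrow(map)) {
    abort("`labels` must have one column per map marker.")
  }
  if (is.character(labels)) {
    idx <- match(labels, founder_ids)
    if (any(!is.na(labels) & is.na(idx))) {
      abort("All non-NA labels must be members of `founder_ids`.")
    }
    labels <- matrix(idx, nrow(labels), ncol(labels))
  }
  storage.mode(labels) <- "integer"
  if (any(!is.na(labels) & (labels < 1L | labels > length(founder_ids)))) {
    abort("Integer labels must index `founder_ids`.")
  }
  if (is.null(line_ids)) {
    line_ids <- rownames(labels) %||% sprintf("line_%04d", seq_len(nrow(labels)))
  }
  structure(
    list(origin = labels, founder_ids = founder_ids, map = map, spec = spec,
         scheme = scheme, line_ids = line_ids, provenance = provenance,
         posteriors = NULL),
    class = "origin_matrix"
  )
}

new_origin_matrix <- function(origin, geno, provenance, posteriors = NULL) {
  structure(
    list(origin = origin, founder_ids = geno$founders$ids, map = geno$map,
         spec = geno$spec, scheme = geno$scheme, line_ids = geno$line_ids,
         provenance = provenance, posteriors = posteriors),
    class = "origin_matrix"
  )
}

#' @export
print.origin_matrix <- function(x, ...) {
  cat(sprintf("<origin_matrix> %d lines x %d markers, %d founders, provenance=%s\n",
              nrow(x$origin), ncol(x$origin), length(x$founder_ids), x$provenance))
  invisible(x)
}

#' Infer founder origin along each line with a hidden Markov model
#'
#' Hidden state = founder at each marker. Emission: the founder's allele with
#' probability `1 - error_rate`, the alternative otherwise; missing calls are
#' uninformative. Transition between consecutive markers: the total switch
#' probability is the Haldane recombination fraction
#' r = (1 - exp(-2 d)) / 2 for map distance d (Morgans), spread uniformly
#' over the alternative founders; distances below `min_d_cm` are clamped so
#' transition probabilities never vanish. The returned labels are the Viterbi
#' path; per-marker posterior founder probabilities (forward-backward) are
#' retained for regression-based QTL scans.
#'
#' Intended for multi-parent (e.g. 8-founder MAGIC) data; it also runs on
#' biparental data, where it reduces to direct allele matching when the data
#' are noiseless, but [assign_parental_origin()] is the preferred route
#' there.
#'
#' @param geno A [genotype_lines()] object.
#' @param error_rate Assumed per-call genotyping error, in `[0, 0.5)`.
#' @param min_d_cm Minimum inter-marker distance (cM) used in transitions.
#' @param keep_posteriors Retain the lines x markers x founders posterior
#'   array (needed by [scan_lod()] for multi-parent populations).
#' @return An `origin_matrix` with `provenance = "hmm"`.
#' @export
infer_founder_mosaic_hmm <- function(geno, error_rate = 0.01, min_d_cm = 1e-6,
                                     keep_posteriors = TRUE) {
  if (!is.finite(error_rate) || error_rate < 0 || error_rate >= 0.5) {
    abort("`error_rate` must lie in [0, 0.5).")
  }
  K <- n_founders(geno$founders)
  if (K < 2L) abort("Need at least 2 founders.")
  map <- geno$map
  alleles <- geno$founders$alleles
  calls <- geno$calls
  n <- nrow(calls)
  m <- ncol(calls)

  chroms <- unique(map$chrom)
  chrom_idx <- lapply(chroms, function(ch) which(map$chrom == ch))
  # per chromosome: switch probabilities between consecutive markers
  rswitch <- lapply(chrom_idx, function(idx) {
    d <- pmax(diff(map$pos_cm[idx]), min_d_cm) / 100
    0.5 * (1 - exp(-2 * d))
  })

  e1 <- max(1 - error_rate, 1e-12)
  e0 <- max(error_rate, 1e-12)

  lab <- matrix(NA_integer_, n, m, dimnames = dimnames(calls))
  post <- if (keep_posteriors) array(NA_real_, c(n, m, K)) else NULL

  for (i in seq_len(n)) {
    for (ci in seq_along(chrom_idx)) {
      idx <- chrom_idx[[ci]]
      t_len <- length(idx)
      obs <- calls[i, idx]
      # emission matrix t_len x K
      em <- matrix(1, t_len, K)
      for (k in seq_len(K)) {
        ak <- alleles[k, idx]
        known <- !is.na(obs)
        em[known, k] <- ifelse(obs[known] == ak[known], e1, e0)
      }
      r <- rswitch[[ci]]
      hmm <- hmm_chrom(em, r, K)
      lab[i, idx] <- hmm$path
      if (keep_posteriors) post[i, idx, ] <- hmm$gamma
    }
  }
  new_origin_matrix(lab, geno, provenance = "hmm", posteriors = post)
}

# Forward-backward + Viterbi for one chromosome with the uniform-switch
# transition structure: P(stay) = 1 - r, P(each other state) = r/(K-1).
hmm_chrom <- function(em, r, K) {
  t_len <- nrow(em)
  prior <- rep(1 / K, K)
  # forward (scaled)
  alpha <- matrix(0, t_len, K)
  a <- prior * em[1L, ]
  s <- sum(a)
  if (s <= 0) { a <- prior; s <- 1 }
  alpha[1L, ] <- a / s
  if (t_len > 1L) {
    for (t in 2:t_len) {
      rt <- r[t - 1L]
      stay <- 1 - rt
      move <- rt / (K - 1)
      pred <- (stay - move) * alpha[t - 1L, ] + move # * sum(alpha)=1
      a <- pred * em[t, ]
      s <- sum(a)
      if (s <= 0) { a <- pred; s <- sum(a) }
      alpha[t, ] <- a / s
    }
  }
  # backward (scaled)
  beta <- matrix(0, t_len, K)
  beta[t_len, ] <- 1
  if (t_len > 1L) {
    for (t in (t_len - 1L):1L) {
      rt <- r[t]
      stay <- 1 - rt
      move <- rt / (K - 1)
      bb <- beta[t + 1L, ] * em[t + 1L, ]
      b <- (stay - move) * bb + move * sum(bb)
      beta[t, ] <- b / sum(b)
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)

  # Viterbi in log space with the O(K) max trick
  lem <- log(em)
  delta <- log(prior) + lem[1L, ]
  back <- matrix(0L, t_len, K)
  if (t_len > 1L) {
    for (t in 2:t_len) {
      rt <- r[t - 1L]
      lstay <- log(1 - rt)
      lmove <- log(rt / (K - 1))
      best <- which.max(delta)
      stay_score <- delta + lstay
      move_score <- delta[best] + lmove
      # for state == best, the off-diagonal max comes from the runner-up
      d2 <- delta
      d2[best] <- -Inf
      best2 <- which.max(d2)
      move_from <- rep(best, K)
      move_score_k <- rep(move_score, K)
      move_score_k[best] <- delta[best2] + lmove
      move_from[best] <- best2
      take_stay <- stay_score >= move_score_k
      back[t, ] <- ifelse(take_stay, seq_len(K), move_from)
      delta <- ifelse(take_stay, stay_score, move_score_k) + lem[t, ]
    }
  }
  path <- integer(t_len)
  path[t_len] <- which.max(delta)
  if (t_len > 1L) {
    for (t in (t_len - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
  }
  list(path = path, gamma = gamma)
}

#' Detect recombination breakpoints from origin labels
#'
#' Scans consecutive informative (non-unknown) markers within each
#' chromosome; every change of founder label is one breakpoint, placed at the
#' physical midpoint of the flanking informative-marker interval. Runs of
#' unknown labels never create or absorb breakpoints. By default an isolated
#' single-marker label whose informative neighbours agree with each other but
#' not with it is treated as genotyping error and relabelled unknown before
#' scanning (`smooth = FALSE` disables this).
#'
#' @param origin An `origin_matrix`.
#' @param smooth Apply singleton smoothing (default `TRUE`).
#' @param quiet Suppress the warning about chromosomes with fewer than two
#'   informative markers.
#' @return A tibble of class `breakpoint_set` with columns `line` (a factor
#'   whose levels are all line ids, so lines without events keep a level),
#'   `chrom`, `left_marker`, `right_marker`, `left_mb`, `right_mb`, `pos_mb`
#'   (the interval midpoint), `left_founder`, `right_founder`.
#' @export
detect_breakpoints <- function(origin, smooth = TRUE, quiet = FALSE) {
  map <- origin$map
  lab <- origin$origin
  n <- nrow(lab)
  chroms <- unique(map$chrom)
  ids <- origin$founder_ids
  sparse_chroms <- 0L

  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    idx <- which(map$chrom == chroms[ci])
    pos <- map$pos_mb[idx]
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      v <- lab[i, idx]
      if (sum(!is.na(v)) < 2L) {
        sparse_chroms <- sparse_chroms + 1L
        next
      }
      chg <- label_changes(v, smooth)
      if (is.null(chg)) next
      li <- chg[[1L]]
      ri <- chg[[2L]]
      rows[[i]] <- tibble(
        line = origin$line_ids[i], chrom = chroms[ci],
        left_marker = map$marker[idx[li]], right_marker = map$marker[idx[ri]],
        left_mb = pos[li], right_mb = pos[ri],
        pos_mb = (pos[li] + pos[ri]) / 2,
        left_founder = ids[v[li]], right_founder = ids[v[ri]]
      )
    }
    out[[ci]] <- list_rbind(rows)
  }
  if (!quiet && sparse_chroms > 0L) {
    warn(sprintf("%d line-chromosome combinations had fewer than 2 informative markers; they yield no breakpoints.",
                 sparse_chroms))
  }
  bps <- list_rbind(out)
  if (nrow(bps) == 0L) {
    bps <- tibble(line = character(), chrom = integer(),
                  left_marker = character(), right_marker = character(),
                  left_mb = numeric(), right_mb = numeric(), pos_mb = numeric(),
                  left_founder = character(), right_founder = character())
  }
  as_breakpoint_set(bps, line_ids = origin$line_ids, scheme = origin$scheme)
}

#' Construct a breakpoint set from a plain data frame
#'
#' Mostly useful for tests and for importing externally computed
#' breakpoints. `line` becomes a factor over `line_ids` so that lines with
#' zero events stay represented.
#'
#' @param df A data frame with at least `line`, `chrom`, `pos_mb`.
#' @param line_ids All line ids in the population (defaults to the ids seen).
#' @param scheme Optional population tag.
#' @return A `breakpoint_set` tibble, sorted by line, chromosome, position.
#' @export
as_breakpoint_set <- function(df, line_ids = NULL, scheme = NULL) {
  if (is.null(line_ids)) line_ids <- unique(as.character(df$line))
  df <- as_tibble(df)
  df$line <- factor(as.character(df$line), levels = line_ids)
  df <- arrange(df, .data$line, .data$chrom, .data$pos_mb)
  attr(df, "scheme") <- scheme
  class(df) <- c("breakpoint_set", class(df))
  df
}

#' Per-line recombination event counts
#'
#' @param bps A `breakpoint_set`.
#' @return A tibble with `line` and `events` (zero for lines without
#'   breakpoints).
#' @export
events_per_line <- function(bps) {
  tab <- table(bps$line)
  tibble(line = names(tab), events = as.integer(tab))
}

#' Chromosomal segment lengths between consecutive breakpoints
#'
#' Segments run from the chromosome start through each breakpoint midpoint to
#' the chromosome end, for every line and chromosome (one full-length segment
#' when a chromosome has no breakpoint). The founder label of each segment is
#' taken from the flanking breakpoint records where available and is `NA` for
#' chromosomes without breakpoints.
#'
#' @param bps A `breakpoint_set`.
#' @param spec The [genome_spec()].
#' @return A tibble with `line`, `chrom`, `start_mb`, `end_mb`, `length_mb`,
#'   `founder`.
#' @export
segment_lengths <- function(bps, spec) {
  lines <- levels(bps$line)
  key <- paste(as.integer(bps$line), bps$chrom, sep = ":")
  lf <- if ("left_founder" %in% names(bps)) bps$left_founder else rep(NA_character_, nrow(bps))
  rf <- if ("right_founder" %in% names(bps)) bps$right_founder else rep(NA_character_, nrow(bps))
  split_pos <- split(bps$pos_mb, key)
  split_lf <- split(lf, key)
  split_rf <- split(rf, key)

  out <- vector("list", length(lines) * nrow(spec))
  z <- 1L
  for (i in seq_along(lines)) {
    for (ci in seq_len(nrow(spec))) {
      k <- paste(i, spec$chrom[ci], sep = ":")
      pos <- split_pos[[k]]
      l <- spec$length_mb[ci]
      if (is.null(pos) || !length(pos)) {
        out[[z]] <- tibble(line = lines[i], chrom = spec$chrom[ci],
                           start_mb = 0, end_mb = l, length_mb = l,
                           founder = NA_character_)
      } else {
        o <- order(pos)
        pos <- pos[o]
        fndr <- c(split_lf[[k]][o][1L], split_rf[[k]][o])
        b <- c(0, pos, l)
        out[[z]] <- tibble(line = lines[i], chrom = spec$chrom[ci],
                           start_mb = b[-length(b)], end_mb = b[-1L],
                           length_mb = diff(b), founder = fndr)
      }
      z <- z + 1L
    }
  }
  list_rbind(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
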