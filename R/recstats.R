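#' Summarise recombination events over the lines of a population
#'
#' @param bps A `breakpoint_set` (see [detect_breakpoints()]).
#' @return A one-row tibble: `scheme`, `n_lines`, `total_events`,
#'   `mean_events`, `sd_events` (n-1 denominator; 0 with `sd_degenerate =
#'   TRUE` for a single line), `min_events`, `max_events`.
#' @export
summarize_events <- function(bps) {
  ev <- events_per_line(bps)
  if (nrow(ev) < 1L) abort("The population has no lines.")
  degenerate <- nrow(ev) < 2L
  tibble(
    scheme = attr(bps, "scheme") %||% NA_character_,
    n_lines = nrow(ev),
    total_events = sum(ev$events),
    mean_events = mean(ev$events),
    sd_events = if (degenerate) 0 else sd(ev$events),
    sd_degenerate = degenerate,
    min_events = min(ev$events),
    max_events = max(ev$events)
  )
}

#' Windowed recombination frequency in cM/Mb
#'
#' Tiles each chromosome with physical windows of `window_mb` (the terminal
#' window may be shorter), optionally samples `n_lines_sample` lines without
#' replacement, and for each window counts the sampled lines with at least
#' one breakpoint midpoint inside the half-open window. The frequency is the
#' recombinant-line fraction expressed in centiMorgans (fraction x 100)
#' divided by the true window width:
#' `freq = 100 * (k / N) / width_mb` cM/Mb. For the default 2-Mb windows
#' this caps at 50 cM/Mb when every line recombines in the window.
#'
#' @param bps A `breakpoint_set`.
#' @param spec The [genome_spec()].
#' @param window_mb Window width in Mb (default 2, must be positive).
#' @param n_lines_sample Number of lines to sample (default: all lines).
#' @param seed Seed for the line sampling.
#' @return A tibble: `chrom`, `start_mb`, `end_mb`, `width_mb`, `k`, `n`,
#'   `freq_cm_mb`.
#' @export
windowed_recfreq <- function(bps, spec, window_mb = 2, n_lines_sample = NULL,
                             seed = NULL) {
  if (!is.finite(window_mb) || window_mb <= 0) abort("`window_mb` must be positive.")
  lines <- levels(bps$line)
  if (!is.null(n_lines_sample)) {
    if (n_lines_sample > length(lines)) {
      abort("`n_lines_sample` exceeds the number of lines (sampling is without replacement).")
    }
    pick <- function() sample(lines, n_lines_sample)
    lines <- if (!is.null(seed)) withr::with_seed(seed, pick()) else pick()
    bps <- bps[as.character(bps$line) %in% lines, ]
  }
  n <- length(lines)

  out <- vector("list", nrow(spec))
  for (ci in seq_len(nrow(spec))) {
    l <- spec$length_mb[ci]
    starts <- seq(0, l, by = window_mb)
    if (starts[length(starts)] >= l) starts <- starts[-length(starts)]
    ends <- pmin(starts + window_mb, l)
    sub <- bps[bps$chrom == spec$chrom[ci], ]
    k <- integer(length(starts))
    if (nrow(sub) > 0L) {
      wi <- findInterval(sub$pos_mb, starts)
      ok <- wi >= 1L & sub$pos_mb < ends[pmax(wi, 1L)]
      tab <- tapply(as.character(sub$line[ok]), wi[ok], function(x) length(unique(x)))
      k[as.integer(names(tab))] <- as.integer(tab)
    }
    out[[ci]] <- tibble(
      chrom = spec$chrom[ci], start_mb = starts, end_mb = ends,
      width_mb = ends - starts, k = k, n = n,
      freq_cm_mb = 100 * (k / n) / (ends - starts)
    )
  }
  list_rbind(out)
}

#' One-way ANOVA of per-line event counts across populations
#'
#' Classical fixed-effects one-way analysis of variance (equal-variance F
#' test of the between/within mean-square ratio), as used to compare
#' recombination event counts across population types.
#'
#' @param data Either a data frame with a value and a group column, or a
#'   named list of numeric vectors (one per population).
#' @param value,group Column names (tidy-eval) when `data` is a data frame.
#'   Defaults `events` and `scheme`.
#' @return A tibble: `statistic` (F), `df_between`, `df_within`, `p_value`,
#'   `n_groups`.
#' @export
#' @examples
#' anova_one_way(list(a = c(1, 2, 3), b = c(4, 5, 6)))
anova_one_way <- function(data, value = NULL, group = NULL) {
  if (is.list(data) && !is.data.frame(data)) {
    if (is.null(names(data))) names(data) <- sprintf("g%d", seq_along(data))
    df <- tibble(
      value = unlist(data, use.names = FALSE),
      group = rep(names(data), lengths(data))
    )
  } else {
    vq <- enquo(value)
    gq <- enquo(group)
    v <- if (rlang::quo_is_null(vq)) data[["events"]] else eval_tidy(vq, data)
    g <- if (rlang::quo_is_null(gq)) data[["scheme"]] else eval_tidy(gq, data)
    df <- tibble(value = v, group = as.character(g))
  }
  sizes <- table(df$group)
  if (length(sizes) < 2L) abort("Need at least 2 groups.")
  if (any(sizes < 2L)) abort("Every group needs at least 2 observations.")
  ft <- oneway.test(value ~ group, data = df, var.equal = TRUE)
  tibble(
    statistic = unname(ft$statistic),
    df_between = unname(ft$parameter[1L]),
    df_within = unname(ft$parameter[2L]),
    p_value = unname(ft$p.value),
    n_groups = length(sizes)
  )
}
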