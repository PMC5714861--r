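# Internal haplotype-mosaic machinery.
#
# A homolog on one chromosome is a list(b, f): b is the numeric boundary
# vector 0 = b[1] < ... < b[k+1] = L (Mb, 0-based half-open segments) and f
# the integer founder code of each of the k segments; adjacent segments
# always differ. A "genome" is a list of such homologs, one per chromosome;
# a line is list(h1 = genome, h2 = genome).

founder_genome <- function(code, spec) {
  lapply(seq_len(nrow(spec)), function(i) {
    list(b = c(0, spec$length_mb[i]), f = as.integer(code))
  })
}

merge_adjacent <- function(b, f) {
  k <- length(f)
  if (k <= 1L) return(list(b = b, f = f))
  chg <- f[-1L] != f[-k]
  run_start <- c(TRUE, chg)
  run_end <- c(chg, TRUE)
  list(b = c(b[1L], b[-1L][run_end]), f = f[run_start])
}

# Extract the piece of homolog h covering [s, e) as (boundaries, founders).
slice_homolog <- function(h, s, e) {
  b <- h$b
  j0 <- findInterval(s, b)
  j0 <- min(max(j0, 1L), length(h$f))
  j1 <- findInterval(e, b, left.open = TRUE)
  j1 <- min(max(j1, j0), length(h$f))
  inner <- if (j1 > j0) b[(j0 + 1L):j1] else numeric(0)
  list(b = c(s, inner, e), f = h$f[j0:j1])
}

# One recombined chromosome: alternate between homologs hA/hB at `cuts`,
# starting from hA if first == 1.
splice_homologs <- function(hA, hB, cuts, first) {
  L <- hA$b[length(hA$b)]
  if (length(cuts) == 0L) {
    return(if (first == 1L) hA else hB)
  }
  pts <- c(0, cuts, L)
  parts_b <- vector("list", length(pts) - 1L)
  parts_f <- vector("list", length(pts) - 1L)
  src <- first
  for (i in seq_len(length(pts) - 1L)) {
    h <- if (src == 1L) hA else hB
    piece <- slice_homolog(h, pts[i], pts[i + 1L])
    parts_b[[i]] <- piece$b[-length(piece$b)]
    parts_f[[i]] <- piece$f
    src <- 3L - src
  }
  b <- c(unlist(parts_b), L)
  f <- unlist(parts_f)
  merge_adjacent(b, f)
}

# Per-chromosome meiosis context: genetic length and the piecewise-linear
# cM -> Mb interpolation anchored at the chromosome ends and the markers.
make_meiosis_ctx <- function(map, spec) {
  lapply(seq_len(nrow(spec)), function(i) {
    m <- map[map$chrom == spec$chrom[i], ]
    cm <- c(0, m$pos_cm, spec$length_cm[i])
    mb <- c(0, m$pos_mb, spec$length_mb[i])
    keep <- !duplicated(cbind(cm, mb))
    list(l_cm = spec$length_cm[i], l_mb = spec$length_mb[i],
         cm = cm[keep], mb = mb[keep])
  })
}

cm_to_mb <- function(u, ctx) {
  if (length(u) == 0L) return(numeric(0))
  cm <- ctx$cm
  mb <- ctx$mb
  i <- findInterval(u, cm, all.inside = TRUE)
  # skip zero-width genetic intervals (plateaus): place at their start
  w <- cm[i + 1L] - cm[i]
  frac <- ifelse(w > 0, (u - cm[i]) / w, 0)
  mb[i] + frac * (mb[i + 1L] - mb[i])
}

# A full gamete: per chromosome, Poisson(L/100) crossovers at positions
# uniform on the genetic scale, mapped to Mb; no interference (Haldane).
gamete_genome <- function(line, ctx) {
  lapply(seq_along(ctx), function(i) {
    cc <- ctx[[i]]
    n <- if (cc$l_cm > 0) rpois(1L, cc$l_cm / 100) else 0L
    cuts <- if (n > 0L) {
      x <- sort(cm_to_mb(runif(n, 0, cc$l_cm), cc))
      x <- x[x > 0 & x < cc$l_mb]
      x[!duplicated(x)]
    } else {
      numeric(0)
    }
    first <- if (runif(1) < 0.5) 1L else 2L
    splice_homologs(line$h1[[i]], line$h2[[i]], cuts, first)
  })
}

cross_lines <- function(mother, father, ctx) {
  list(h1 = gamete_genome(mother, ctx), h2 = gamete_genome(father, ctx))
}

self_line <- function(line, ctx) {
  list(h1 = gamete_genome(line, ctx), h2 = gamete_genome(line, ctx))
}

# Homozygous consensus of a line on one chromosome: atomic segments where
# both homologs carry the same founder keep that label; heterozygous
# stretches are dropped (unknown). Returns list(b0, b1, f) of known segments.
consensus_segments <- function(h1, h2) {
  b <- sort(unique(c(h1$b, h2$b)))
  n <- length(b) - 1L
  mids <- (b[-1L] + b[-(n + 1L)]) / 2
  f1 <- h1$f[pmin(findInterval(mids, h1$b), length(h1$f))]
  f2 <- h2$f[pmin(findInterval(mids, h2$b), length(h2$f))]
  known <- f1 == f2
  list(start = b[-(n + 1L)][known], end = b[-1L][known], f = f1[known])
}

# True per-line event count: founder switches along the homozygous consensus,
# summed over chromosomes; unknown (heterozygous) stretches never count.
count_consensus_junctions <- function(line) {
  total <- 0L
  for (i in seq_along(line$h1)) {
    cs <- consensus_segments(line$h1[[i]], line$h2[[i]])
    if (length(cs$f) > 1L) total <- total + sum(cs$f[-1L] != cs$f[-length(cs$f)])
  }
  total
}

# Founder code of homolog h at physical positions pos.
founder_at <- function(h, pos) {
  h$f[pmin(pmax(findInterval(pos, h$b), 1L), length(h$f))]
}
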