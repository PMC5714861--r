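#' Founder haplotypes for a population design
#'
#' Creates the founder allele matrix used by the simulator and by
#' origin assignment. Biparental designs (DH, RIL, IBM) use two founders
#' that differ at every marker (alleles coded 0 for the first founder and 1
#' for the second, which is only a labelling convention). Multi-parent
#' designs draw random biallelic founder alleles, constrained so that every
#' marker is polymorphic across the founder panel.
#'
#' @param map A genetic map tibble from [build_genetic_map()].
#' @param n_founders 2 (biparental) or more (e.g. 8 for MAGIC).
#' @param ids Optional founder names. Defaults: `c("B73","Mo17")` for two
#'   founders; the classical eight-founder maize panel for eight.
#' @param seed Optional seed for the random multi-parent allele draw.
#' @return An object of class `founder_set`: a list with `ids` and an
#'   `alleles` matrix (founders x markers, entries 0/1).
#' @export
founder_set <- function(map, n_founders = 2, ids = NULL, seed = NULL) {
  if (n_founders < 2) abort("`n_founders` must be at least 2.")
  m <- nrow(map)
  if (is.null(ids)) {
    ids <- if (n_founders == 2) {
      c("B73", "Mo17")
    } else if (n_founders == 8) {
      c("A632", "B73", "B96", "F7", "H99", "HP301", "Mo17", "W153R")
    } else {
      sprintf("F%02d", seq_len(n_founders))
    }
  }
  if (length(ids) != n_founders) abort("`ids` must have length `n_founders`.")

  draw <- function() {
    if (n_founders == 2) {
      alleles <- rbind(rep(0L, m), rep(1L, m))
    } else {
      alleles <- matrix(rbinom(n_founders * m, 1, 0.5), nrow = n_founders)
      mono <- which(matrixStats_colAllEqual(alleles))
      for (j in mono) {
        i <- sample.int(n_founders, 1)
        alleles[i, j] <- 1L - alleles[i, j]
      }
    }
    alleles
  }
  alleles <- if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
  dimnames(alleles) <- list(ids, map$marker)
  structure(list(ids = ids, alleles = alleles), class = "founder_set")
}

# columns where all founders carry the same allele
matrixStats_colAllEqual <- function(x) {
  apply(x, 2, function(col) all(col == col[1]))
}

#' @export
print.founder_set <- function(x, ...) {
  cat(sprintf("<founder_set> %d founders x %d markers\n",
              length(x$ids), ncol(x$alleles)))
  cat("founders:", paste(x$ids, collapse = ", "), "\n")
  invisible(x)
}

#' Number of founders in a founder set
#' @param founders A [founder_set()].
#' @return Integer count.
#' @export
n_founders <- function(founders) length(founders$ids)
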