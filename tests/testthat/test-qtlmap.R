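spec10 <- maize_genome_spec()
map_q <- build_genetic_map(spec10, 500, placement = "random", seed = 51)
f2 <- founder_set(map_q)
pop_dh <- simulate_population("dh", f2, map_q, spec10, 200, seed = 52)
org_dh <- assign_parental_origin(genotype_lines(pop_dh))

test_that("null phenotypes are seeded, standard normal, and trait means behave", {
  y1 <- simulate_null_phenotypes(200, 1000, seed = 3)
  y2 <- simulate_null_phenotypes(200, 1000, seed = 3)
  expect_identical(y1, y2)
  se <- 1 / sqrt(200)
  # 1,000 traits: allow the usual multiplicity head-room on the 3-SE rule
  expect_lt(mean(abs(colMeans(y1)) > 3 * se), 0.01)
  expect_lt(abs(mean(y1)), 3 / sqrt(200 * 1000))
  expect_error(simulate_null_phenotypes(0, 5), ">= 1")
})

test_that("a planted QTL explains close to its nominal variance fraction", {
  code <- org_dh$origin[, 250] - 1
  y <- simulate_qtl_phenotypes(code, 100, h2 = 0.5, seed = 4)
  r2 <- apply(y, 2, function(yy) summary(lm(yy ~ code))$r.squared)
  expect_gt(mean(r2), 0.4)
  expect_lt(mean(r2), 0.6)
  expect_error(simulate_qtl_phenotypes(rep(1, 50), 5), "zero variance")
})

test_that("LOD is invariant to affine phenotype transforms and capped on perfect fits", {
  y <- simulate_null_phenotypes(200, 1, seed = 5)[, 1]
  p1 <- scan_lod(org_dh, y)
  p2 <- scan_lod(org_dh, 5 * y - 2)
  expect_equal(p1$lod, p2$lod, tolerance = 1e-9)
  expect_true(all(p1$lod >= 0))

  perfect <- as.numeric(org_dh$origin[, 100] - 1)
  perfect[is.na(perfect)] <- 0.5
  prof <- scan_lod(org_dh, perfect + rnorm(200, sd = 1e-8))
  expect_equal(max(prof$lod), 300)

  expect_error(scan_lod(org_dh, rep(1, 200)), "positive variance")
})

test_that("the null single-marker LOD mean matches the chi-square expectation", {
  y <- simulate_null_phenotypes(200, 1000, seed = 6)
  lod <- recombkit:::lod_matrix(org_dh, y)
  expected <- log10(exp(1)) / 2  # (df/2) * log10(e), df = 1
  for (j in c(50, 250, 450)) {
    expect_lt(abs(mean(lod[j, ]) - expected) / expected, 0.15)
  }
})

test_that("permuted phenotypes and fresh null traits give the same max-LOD law", {
  y <- simulate_null_phenotypes(200, 1, seed = 7)[, 1]
  perms <- withr::with_seed(8, replicate(200, sample(y)))
  fresh <- simulate_null_phenotypes(200, 200, seed = 9)
  mx_p <- apply(recombkit:::lod_matrix(org_dh, perms), 2, max)
  mx_f <- apply(recombkit:::lod_matrix(org_dh, fresh), 2, max)
  expect_gt(stats::ks.test(mx_p, mx_f)$p.value, 0.01)
})

test_that("QTL calls interpolate 2-LOD support intervals on a triangular profile", {
  pos <- seq(0, 100, by = 2)
  prof <- tibble::tibble(trait = "t1", marker = sprintf("m%d", seq_along(pos)),
                         chrom = 1, pos_cm = pos, pos_mb = pos,
                         lod = pmax(10 - 0.2 * abs(pos - 50), 0))
  calls <- call_qtl(prof, threshold = 3, drop = 2)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$peak_mb, 50)
  expect_equal(calls$start_mb, 40)
  expect_equal(calls$end_mb, 60)
  expect_equal(calls$length_mb, 20)

  # profile everywhere below the threshold: no calls
  low <- dplyr::mutate(prof, lod = lod / 10)
  expect_equal(nrow(call_qtl(low, threshold = 3)), 0L)
  expect_error(call_qtl(prof, threshold = 0), "positive")
})

test_that("support intervals truncate at terminal markers", {
  pos <- seq(0, 100, by = 2)
  prof <- tibble::tibble(trait = "t1", marker = sprintf("m%d", seq_along(pos)),
                         chrom = 1, pos_cm = pos, pos_mb = pos,
                         lod = 6 - 0.02 * pos)  # peak at the chromosome start
  calls <- call_qtl(prof, threshold = 3, drop = 2)
  expect_equal(calls$start_mb, 0)
  expect_equal(calls$peak_mb, 0)
  expect_equal(calls$end_mb, 100)  # never falls 2 LOD below the peak
})

test_that("a strong planted QTL is located at its marker with a covering interval", {
  code <- org_dh$origin[, 300] - 1
  truth_mb <- map_q$pos_mb[300]
  truth_chrom <- map_q$chrom[300]
  y <- simulate_qtl_phenotypes(code, 1, h2 = 0.5, seed = 10)[, 1]
  calls <- call_qtl(scan_lod(org_dh, y), threshold = 3)
  hit <- calls[calls$chrom == truth_chrom, ]
  expect_equal(nrow(hit), 1L)
  expect_lte(hit$start_mb, truth_mb)
  expect_gte(hit$end_mb, truth_mb)
  expect_equal(hit$peak_lod, max(calls$peak_lod))
})

test_that("denser marker maps localise a planted QTL more accurately", {
  # the causal marker is kept in the full map but dropped from the sparse one,
  # so the sparse scan can at best localise to a flanking marker
  half <- seq(1, nrow(map_q), by = 2)
  idx <- half[150] + 1
  code <- org_dh$origin[, idx] - 1
  truth_mb <- map_q$pos_mb[idx]
  truth_ch <- map_q$chrom[idx]
  y <- simulate_qtl_phenotypes(code, 100, h2 = 0.3, seed = 11)

  org_half <- origin_matrix(org_dh$origin[, half], map_q[half, ], f2$ids,
                            spec = spec10, scheme = "dh")
  loc <- function(org) {
    lod <- recombkit:::lod_matrix(org, y)
    m <- org$map
    err <- c(); covered <- 0L
    for (tr in seq_len(ncol(y))) {
      cc <- recombkit:::call_qtl_vec(m$chrom, m$pos_mb, lod[, tr], 3, 2)
      cc <- cc[cc$chrom == truth_ch, ]
      if (nrow(cc)) {
        err <- c(err, abs(cc$peak_mb[1] - truth_mb))
        covered <- covered +
          (cc$start_mb[1] <= truth_mb && cc$end_mb[1] >= truth_mb)
      }
    }
    list(err = mean(err), coverage = covered / ncol(y))
  }
  full <- loc(org_dh)
  sparse <- loc(org_half)
  expect_lt(full$err, sparse$err)
  expect_gte(full$coverage, 0.9)
  expect_gte(sparse$coverage, 0.9)
})

test_that("the map-resolution experiment is deterministic and validates inputs", {
  pops <- list(dh = pop_dh)
  m1 <- map_resolution_experiment(pops, n_traits = 40, n_lines = 150, seed = 12)
  m2 <- map_resolution_experiment(pops, n_traits = 40, n_lines = 150, seed = 12)
  expect_identical(m1, m2)
  expect_error(map_resolution_experiment(list(pop_dh), n_traits = 5), "named list")
  expect_error(map_resolution_experiment(pops, n_traits = 5, n_lines = 500),
               "500 requested")
})

test_that("the multi-founder threshold admits the requested fraction of traits", {
  map2 <- build_genetic_map(spec10, 800, placement = "random", seed = 53)
  f8 <- founder_set(map2, 8, seed = 54)
  pop_m <- simulate_population("magic", f8, map2, spec10, 60, seed = 55)
  mr <- map_resolution_experiment(list(magic = pop_m), n_traits = 50, n_lines = 60,
                                  magic_trait_fraction = 0.4, seed = 56)
  calls <- attr(mr, "calls")
  # fraction of traits with at least one QTL equals the requested fraction
  # (up to the quantile's discreteness)
  expect_equal(length(unique(calls$trait)) / 50, 0.4, tolerance = 0.05)
  expect_gt(mr$threshold, 1.5)
})
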