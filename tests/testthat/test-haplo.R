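spec1 <- one_chrom_spec(100, 100)
map5 <- tibble::tibble(marker = sprintf("m%d", 1:5), chrom = 1,
                       pos_cm = c(10, 20, 30, 40, 50),
                       pos_mb = c(10, 20, 30, 40, 50))
f2 <- make_founders(rbind(rep(0L, 5), rep(1L, 5)), c("A", "B"))

test_that("direct origin assignment matches alleles and passes missing calls through", {
  calls <- rbind(rep(0L, 5),                      # identical to founder A
                 c(0L, 0L, NA, 1L, 1L))           # A,A,NA,B,B
  geno <- make_geno(calls, map5, f2, spec1)
  org <- assign_parental_origin(geno)
  expect_equal(unname(org$origin[1, ]), rep(1L, 5))
  expect_equal(unname(org$origin[2, ]), c(1L, 1L, NA, 2L, 2L))
  expect_identical(org$provenance, "direct")

  f8 <- make_founders(matrix(0L, 8, 5))
  expect_error(assign_parental_origin(make_geno(calls, map5, f8)),
               "exactly 2 founders")
})

test_that("breakpoints fall at flanking-interval midpoints and unknown runs never add events", {
  lab <- rbind(c("A", "A", "B", "B", "B"),
               c("A", NA, "B", NA, "B"),
               c("A", "A", "A", "A", "A"))
  org <- origin_matrix(lab, map5, c("A", "B"), spec = spec1)
  bps <- detect_breakpoints(org, quiet = TRUE)
  expect_equal(nrow(bps), 2L)
  # line 1: change between markers at 20 and 30 Mb
  expect_equal(bps$pos_mb[bps$line == "line_0001"], 25)
  # line 2: change between informative markers at 10 and 30 Mb
  expect_equal(bps$pos_mb[bps$line == "line_0002"], 20)
  # zero-event line keeps its factor level
  expect_true("line_0003" %in% levels(bps$line))
  expect_equal(events_per_line(bps)$events, c(1L, 1L, 0L))
})

test_that("singleton smoothing removes isolated labels only when enabled", {
  lab <- rbind(c("A", "A", "B", "A", "A"))
  org <- origin_matrix(lab, map5, c("A", "B"), spec = spec1)
  expect_equal(nrow(detect_breakpoints(org, smooth = TRUE, quiet = TRUE)), 0L)
  expect_equal(nrow(detect_breakpoints(org, smooth = FALSE, quiet = TRUE)), 2L)
})

test_that("segment lengths tile each chromosome and counts equal breakpoints + chromosomes", {
  bps <- as_breakpoint_set(
    tibble::tibble(line = "l1", chrom = 1, pos_mb = 25),
    line_ids = c("l1", "l2")
  )
  segs <- segment_lengths(bps, spec1)
  s1 <- segs[segs$line == "l1", ]
  expect_equal(s1$length_mb, c(25, 75))
  s2 <- segs[segs$line == "l2", ]
  expect_equal(s2$length_mb, 100)

  spec10 <- maize_genome_spec()
  map10 <- build_genetic_map(spec10, 600, placement = "random", seed = 2)
  pop <- simulate_population("ril", founder_set(map10), map10, spec10, 30, seed = 3)
  org <- assign_parental_origin(genotype_lines(pop))
  bb <- detect_breakpoints(org, quiet = TRUE)
  ss <- segment_lengths(bb, spec10)
  per_line <- tapply(ss$length_mb, ss$line, sum)
  expect_true(all(abs(per_line - total_length_mb(spec10)) < 1e-9))
  n_segs <- tapply(ss$length_mb, ss$line, length)
  ev <- events_per_line(bb)
  expect_equal(as.integer(n_segs[ev$line]), ev$events + nrow(spec10))
})

test_that("direct origin labels equal the simulator's consensus truth on noiseless data", {
  spec10 <- maize_genome_spec()
  map10 <- build_genetic_map(spec10, 500, placement = "random", seed = 4)
  pop <- simulate_population("ril", founder_set(map10), map10, spec10, 20, seed = 5)
  org <- assign_parental_origin(genotype_lines(pop))
  for (i in seq_len(pop$n_lines)) {
    ln <- pop$lines[[i]]
    for (ci in seq_len(nrow(spec10))) {
      idx <- which(map10$chrom == spec10$chrom[ci])
      pos <- map10$pos_mb[idx]
      t1 <- recombkit:::founder_at(ln$h1[[ci]], pos)
      t2 <- recombkit:::founder_at(ln$h2[[ci]], pos)
      truth <- ifelse(t1 == t2, t1, NA_integer_)
      expect_equal(unname(org$origin[i, idx]), as.integer(truth))
    }
  }
})

test_that("the founder HMM recovers an unambiguous path exactly and is Bayes-exact on one marker", {
  # founders carry private codes, so emissions identify the state uniquely
  alle <- matrix(rep(1:4, 6), nrow = 4)
  f4 <- make_founders(alle)
  map6 <- tibble::tibble(marker = sprintf("m%d", 1:6), chrom = 1,
                         pos_cm = seq(0, 50, by = 10), pos_mb = seq(0, 50, by = 10))
  calls <- rbind(c(1L, 1L, 3L, 3L, 3L, 2L),
                 c(4L, 4L, 4L, 4L, 4L, 4L))
  org <- infer_founder_mosaic_hmm(make_geno(calls, map6, f4, spec1), error_rate = 0)
  expect_equal(unname(org$origin), unname(calls))

  # single biallelic marker: posterior uniform over allele-compatible founders
  f8 <- make_founders(matrix(c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L), ncol = 1))
  map1 <- tibble::tibble(marker = "m1", chrom = 1, pos_cm = 5, pos_mb = 5)
  org1 <- infer_founder_mosaic_hmm(make_geno(matrix(0L, 1, 1), map1, f8),
                                   error_rate = 0)
  post <- org1$posteriors[1, 1, ]
  expect_equal(post[1:3], rep(1 / 3, 3))
  expect_equal(sum(post[4:8]), 0)

  expect_error(infer_founder_mosaic_hmm(make_geno(calls, map6, f4), error_rate = 0.6),
               "0, 0.5")
})

test_that("the founder HMM is accurate on simulated MAGIC data with genotyping error", {
  spec10 <- maize_genome_spec()
  map10 <- build_genetic_map(spec10, 2000, placement = "random", seed = 31)
  f8 <- founder_set(map10, 8, seed = 32)
  pop <- simulate_population("magic", f8, map10, spec10, 10, seed = 33)
  geno <- genotype_lines(pop, error_rate = 0.01, seed = 34)
  org <- infer_founder_mosaic_hmm(geno, error_rate = 0.01)
  num <- 0; den <- 0
  for (i in seq_len(pop$n_lines)) {
    ln <- pop$lines[[i]]
    for (ci in seq_len(nrow(spec10))) {
      idx <- which(map10$chrom == spec10$chrom[ci])
      pos <- map10$pos_mb[idx]
      t1 <- recombkit:::founder_at(ln$h1[[ci]], pos)
      t2 <- recombkit:::founder_at(ln$h2[[ci]], pos)
      known <- t1 == t2
      num <- num + sum(org$origin[i, idx][known] == t1[known])
      den <- den + sum(known)
    }
  }
  expect_gte(num / den, 0.95)
})

test_that("HMM restricted to two founders matches direct assignment on noiseless data", {
  spec10 <- maize_genome_spec()
  map10 <- build_genetic_map(spec10, 500, placement = "random", seed = 41)
  pop <- simulate_population("ril", founder_set(map10), map10, spec10, 15, seed = 42)
  geno <- genotype_lines(pop)
  bps_direct <- detect_breakpoints(assign_parental_origin(geno), quiet = TRUE)
  bps_hmm <- detect_breakpoints(infer_founder_mosaic_hmm(geno, error_rate = 0.001),
                                quiet = TRUE)
  ev_d <- events_per_line(bps_direct)
  ev_h <- events_per_line(bps_hmm)
  expect_equal(ev_h$events, ev_d$events)
  # every HMM breakpoint lies inside the matching direct flanking interval
  key_d <- paste(bps_direct$line, bps_direct$chrom)
  key_h <- paste(bps_hmm$line, bps_hmm$chrom)
  expect_equal(sort(unique(key_h)), sort(unique(key_d)))
  for (k in unique(key_d)) {
    d <- bps_direct[key_d == k, ]
    h <- bps_hmm[key_h == k, ]
    expect_equal(nrow(h), nrow(d))
    expect_true(all(h$pos_mb >= d$left_mb - 1e-9 & h$pos_mb <= d$right_mb + 1e-9))
  }
})
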