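make_perfect_pair <- function(mseq, flank = 40) {
  m <- mirna_seq("m", mseq)
  comp <- c(4L, 3L, 2L, 1L)[m$codes[1:min(m$M, 20)]]
  site <- paste(NTS[rev(comp)], collapse = "")
  u <- utr_seq("u", paste0(strrep("C", flank), site, strrep("C", flank)))
  sites <- scan_sites(m, u)
  ends <- vapply(sites, `[[`, 0L, "end")
  k <- which(ends == flank + nchar(site))
  if (!length(k)) return(NULL)     # planted window lost to a merge tie
  list(m = m, u = u, site = sites[[k[1]]])
}

test_that("perfect 20-nt complement folds to an all-WC duplex", {
  set.seed(50)
  px <- make_perfect_pair("UGGAAUGUAAAGAAGUAUGUAU")
  d <- fold_duplex(px$m, px$site, px$u)
  expect_equal(d$status, rep(1L, 20))
  expect_equal(unname(d$bulges$total["count"]), 0L)
  expect_lt(d$e_seed, 0)
  expect_lt(d$e_three, 0)
  # additivity: total within one stack term of seed + three
  expect_lte(abs(d$e_total - (d$e_seed + d$e_three)), 3.42 + 1e-9)
  expect_equal(d$seed_boundary, 8L)
})

test_that("seed-only complement leaves the 3' region weak", {
  set.seed(51)
  m <- mirna_seq("m", "UGGAAUGUAAAGAAGUAUGUAU")
  comp <- c(4L, 3L, 2L, 1L)[m$codes[1:8]]
  u <- utr_seq("u", paste0(strrep("C", 12), strrep("A", 12),
                           paste(NTS[rev(comp)], collapse = ""),
                           strrep("C", 30)))
  s <- scan_sites(m, u)
  s <- s[[which.max(vapply(s, `[[`, 0L, "n_wc"))]]
  d <- fold_duplex(m, s, u)
  expect_true(all(d$status[1:8] == 1L))
  expect_lt(d$e_seed, 0)
  expect_gte(d$e_three, d$e_seed)
  expect_error(fold_duplex(m, candidate_site("u", "m", 0, 5, 1, rep(1L, 8),
                                             1:8, 8L, 8L), u),
               "degenerate")
})

test_that("3' DP equals the exhaustive chain-enumeration oracle", {
  # 12-nt toy miRNAs: 3' region is p9..p12 against up to 6 site nts
  set.seed(52)
  params <- default_energy_params()
  n_cases <- 200
  for (i in seq_len(n_cases)) {
    m <- rand_mirna("m", 12)
    comp <- c(4L, 3L, 2L, 1L)[m$codes[1:8]]
    ucod <- c(sample.int(4L, 6, replace = TRUE), rev(comp),
              sample.int(4L, 4, replace = TRUE))
    u <- utr_seq("u", decode_rna(ucod))
    sites <- scan_sites(m, u)
    starts <- vapply(sites, `[[`, 0L, "start")
    k <- which(starts == 6L)
    if (!length(k)) next
    s <- sites[[k[1]]]
    d <- fold_duplex(m, s, u)
    t0 <- {
      st <- pair_status_code(m$codes[8], ucod[s$start + 1])
      if (st <= 2) pair_type_code(m$codes[8], ucod[s$start + 1]) else 0L
    }
    oracle <- oracle_three_prime(m$codes, ucod, s$start, t0, params,
                                 Mc = 12L, Kr = min(s$start, 4L + 4L))
    expect_equal(d$e_three + d$junction, oracle, tolerance = 1e-9)
  }
})

test_that("energy is monotone under WC-to-mismatch point mutations", {
  set.seed(53)
  for (i in 1:40) {
    px <- make_perfect_pair(rand_rna(20))
    if (is.null(px)) next
    d0 <- fold_duplex(px$m, px$site, px$u)
    # mutate one paired UTR nt in the 3' region to a mismatch
    pos <- sample(px$site$start - (1:4), 1)
    codes <- px$u$codes
    a <- px$m$codes[8 + (px$site$start - pos)]
    bad <- which(pair_status_code(rep(a, 4), 1:4) == 3L)[1]
    codes[pos + 1L] <- bad
    u2 <- utr_seq("u2", decode_rna(codes))
    s2 <- scan_sites(px$m, u2)
    starts <- vapply(s2, `[[`, 0L, "start")
    k <- which(starts == px$site$start)
    if (!length(k)) next
    d1 <- fold_duplex(px$m, s2[[k[1]]], u2)
    expect_gte(d1$e_total, d0$e_total - 1e-9)
  }
})

test_that("statuses and dimer codes stay in range on random candidates", {
  set.seed(54)
  m <- rand_mirna("m", 22)
  for (i in 1:30) {
    u <- utr_seq("u", rand_rna(300))
    for (s in scan_sites(m, u)) {
      d <- fold_duplex(m, s, u)
      expect_true(all(d$status %in% 1:4))
      expect_length(d$status, 20)
      expect_true(all(d$dimer_code %in% 1:16))
      expect_length(d$dimer_code, 19)
      expect_equal(d$bulges$total, d$bulges$seed + d$bulges$three)
      # any filter-passing structure has enough pairing to be stable
      expect_lte(d$e_total, 0)
    }
  }
})

test_that("builtin fold matches the exhaustive structure-enumeration oracle", {
  set.seed(55)
  for (i in 1:40) {
    n <- sample(12:15, 1)
    codes <- sample.int(4L, n, replace = TRUE)
    expect_equal(fold_mfe(codes), oracle_fold(codes), tolerance = 1e-9)
    # constrained variant: forbid a random block from pairing
    lo <- sample(1:(n - 3), 1)
    can <- rep(TRUE, n); can[lo:(lo + 3)] <- FALSE
    expect_equal(fold_mfe(codes, can), oracle_fold(codes, can),
                 tolerance = 1e-9)
  }
})

test_that("accessibility is zero-cost in unstructured context and grows in a stem", {
  # all-U seed makes the site poly-A, so an all-A/C neighbourhood is truly
  # unstructured (A:A and A:C never pair)
  m <- mirna_seq("m", paste0(strrep("U", 8), strrep("G", 14)))
  u1 <- utr_seq("u1", paste0(strrep("C", 40), strrep("A", 8), strrep("C", 40)))
  s1 <- scan_sites(m, u1)[[1]]
  expect_equal(s1$start, 40L)
  a1 <- accessibility(u1, s1, dg_duplex = -10)
  expect_equal(a1$dg_open, 0)
  expect_equal(a1$ddg, -10)
  # the same site able to pair a downstream U-block must cost energy to open
  u2 <- utr_seq("u2", paste0(strrep("C", 40), strrep("A", 8), strrep("C", 8),
                             strrep("U", 8), strrep("C", 30)))
  s2 <- scan_sites(m, u2)
  s2 <- s2[[which(vapply(s2, `[[`, 0L, "start") == 40L)[1]]]
  a2 <- accessibility(u2, s2, dg_duplex = -10)
  expect_gt(a2$dg_open, 0)
  expect_gt(a2$ddg, a1$ddg)
  # heuristic fallback is flagged
  a3 <- accessibility(u1, s1, dg_duplex = -10, backend = "heuristic")
  expect_true(a3$fallback)
  expect_true(is.finite(a3$ddg))
})

test_that("energy parameter files override defaults", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("param\tvalue", "stack_GC\t-5.0", "bulge_open\t2.0"), f)
  p <- read_energy_params(f)
  expect_equal(p$stack_wc["G", "C"], -5.0)
  expect_equal(p$bulge_open, 2.0)
  expect_equal(p$mismatch, default_energy_params()$mismatch)
  expect_error(read_energy_params({
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("param\tvalue", "nope\t1"), f2); f2
  }), "unknown")
})
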