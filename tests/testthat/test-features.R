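toy_site <- function(statuses, seed_string, start = 50L, end = NULL,
                     utr_len = 200L, mirna_index = 1:8) {
  if (is.null(end)) end <- start + nchar(seed_string)
  candidate_site("u", "m", start, end, 1L, statuses, mirna_index,
                 n_wc = sum(statuses == 1L), n_match = sum(statuses <= 2L),
                 seed_string = seed_string, utr_length = utr_len)
}

test_that("seed match features follow the six definitions", {
  # all 8 WC and q1 = A (possible when p1 = U)
  s <- toy_site(rep(1L, 8), "GCAUUCCA")
  expect_equal(unname(seed_match_features(s)), rep(1, 6))
  # only p2..p7 WC, q1 not A
  s2 <- toy_site(c(3L, rep(1L, 6), 3L), "GCAUUCCG")
  expect_equal(unname(seed_match_features(s2)), c(1, 0, 0, 0, 0, 0))
  # only p2..p7 WC with literal A opposite p1
  s3 <- toy_site(c(3L, rep(1L, 6), 3L), "GCAUUCCA")
  expect_equal(unname(seed_match_features(s3)), c(1, 1, 0, 0, 0, 0))
})

test_that("seed match flags agree with a brute-force checker on samples", {
  set.seed(60)
  m <- mirna_seq("m", "UGGAAUGUAAAGAAGUAUGUAU")
  for (i in 1:2000) {
    w <- sample.int(4L, 8, replace = TRUE)      # w[k] = nt at q_k
    st <- pair_status_code(m$codes[1:8], w)
    seed_string <- decode_rna(rev(w))
    s <- toy_site(st, seed_string)
    got <- seed_match_features(s)
    wc <- st == 1L
    q1A <- w[1] == 1L
    want <- c(all(wc[2:7]), all(wc[2:7]) && q1A, all(wc[1:7]),
              all(wc[2:8]), all(wc[2:8]) && q1A, all(wc[1:8]))
    expect_equal(unname(got), as.numeric(want))
  }
})

test_that("pairwise and regional features have the documented shape", {
  px <- local({
    m <- mirna_seq("m", "UGGAAUGUAAAGAAGUAUGUAU")
    comp <- c(4L, 3L, 2L, 1L)[m$codes[1:20]]
    u <- utr_seq("u", paste0(strrep("C", 40),
                             paste(NTS[rev(comp)], collapse = ""),
                             strrep("C", 40)))
    sites <- scan_sites(m, u)
    ends <- vapply(sites, `[[`, 0L, "end")
    list(m = m, u = u, s = sites[[which(ends == 60L)[1]]])
  })
  d <- fold_duplex(px$m, px$s, px$u)
  pw <- pairwise_features(d)
  expect_length(pw, 39)
  expect_equal(unname(pw[1:20]), rep(1, 20))
  # dimer codes follow the documented 4x4 encoding of the miRNA sequence
  mcod <- px$m$codes
  expect_equal(unname(pw[21:39]), 4 * (mcod[1:19] - 1) + mcod[2:20])
  rf <- regional_features(d)
  expect_length(rf, 18)
  expect_equal(unname(rf[c("n_wc_seed", "n_wc_three", "n_wc_total")]),
               c(8, 12, 20))
  expect_equal(sum(rf[grep("^bulge", names(rf))]), 0)
})

test_that("regional counts add: seed + three = total on random duplexes", {
  set.seed(61)
  m <- rand_mirna("m", 22)
  checked <- 0
  for (i in 1:25) {
    u <- utr_seq("u", rand_rna(250))
    for (s in scan_sites(m, u)) {
      rf <- regional_features(fold_duplex(m, s, u))
      for (nm in c("wc", "gu", "mismatch", "gap")) {
        expect_equal(rf[[paste0("n_", nm, "_seed")]] +
                       rf[[paste0("n_", nm, "_three")]],
                     rf[[paste0("n_", nm, "_total")]])
      }
      checked <- checked + 1
    }
  }
  expect_gt(checked, 20)
})

test_that("conservation features average the three regions", {
  cons <- rep(0.8, 200)
  u <- utr_seq("u", rand_rna(200), cons = cons)
  s <- toy_site(rep(1L, 8), substr(u$seq, 51, 58))
  expect_equal(unname(conservation_features(s, u)), rep(0.8, 3))
  cons2 <- rep(0.1, 200); cons2[51:58] <- 0.9
  u2 <- utr_seq("u2", u$seq, cons = cons2)
  cf <- conservation_features(s, u2)
  expect_gt(cf["cons_seed"], cf["cons_context5"])
  expect_gt(cf["cons_seed"], cf["cons_context3"])
  # hand-computed mean on a printed toy track over the seed region
  cons3 <- rep(0, 60)
  cons3[51:58] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  u3 <- utr_seq("u3", rand_rna(60), cons = cons3)
  s3 <- toy_site(rep(1L, 8), substr(u3$seq, 51, 58), utr_len = 60L)
  expect_equal(unname(conservation_features(s3, u3)["cons_seed"]), 0.45)
  # context3 runs off the UTR end: absent positions count as 0 over 10
  expect_equal(unname(conservation_features(s3, u3)["cons_context3"]), 0)
})

test_that("context features: poly-A, class separation, boundary truncation", {
  u <- utr_seq("u", strrep("A", 200))
  s <- toy_site(rep(3L, 8), strrep("A", 8))
  cf <- context_features(s, u)
  expect_length(cf, 40)
  expect_equal(unname(cf["comp_A"]), 20)
  expect_equal(unname(cf["comp_AA"]), 18)
  expect_equal(sum(cf[grep("^comp_", names(cf))]), 20 + 18)
  expect_true(all(cf[grep("^pos_", names(cf))] == 1))
  # boundary site: truncated context coded 0 and excluded from counts
  s2 <- toy_site(rep(3L, 8), strrep("A", 8), start = 4L, end = 12L)
  cf2 <- context_features(s2, u)
  expect_equal(unname(cf2[paste0("pos_r", 5:10)]), rep(0, 6))
  expect_equal(unname(cf2["comp_A"]), 14)
  # AU-rich vs GC-rich contexts separate in composition space
  set.seed(62)
  au_scores <- gc_scores <- numeric(30)
  for (i in 1:30) {
    au_ctx <- paste(sample(c("A", "U"), 28, TRUE), collapse = "")
    gc_ctx <- paste(sample(c("G", "C"), 28, TRUE), collapse = "")
    mk <- function(ctx) {
      uu <- utr_seq("x", paste0(strrep("C", 40),
                                substr(ctx, 1, 10), strrep("G", 8),
                                substr(ctx, 11, 20), strrep("C", 40)))
      ss <- toy_site(rep(1L, 8), strrep("G", 8), start = 50L)
      sum(context_features(ss, uu)[c("comp_A", "comp_U")])
    }
    au_scores[i] <- mk(au_ctx); gc_scores[i] <- mk(gc_ctx)
  }
  expect_true(min(au_scores) > max(gc_scores))
})

test_that("location features match the definitions", {
  u <- utr_seq("u", rand_rna(1000))
  s_mid <- toy_site(rep(1L, 8), "AAAAAAAAAAAAAAAAAAAA", start = 400L,
                    end = 420L, utr_len = 1000L)
  expect_equal(unname(location_features(s_mid, u)), c(400, 400, 0.4))
  s0 <- toy_site(rep(1L, 8), "AAAAAAAA", start = 0L, utr_len = 1000L)
  expect_equal(unname(location_features(s0, u)), c(0, 0, 0))
  set.seed(63)
  for (i in 1:50) {
    st <- sample(0:990, 1)
    s <- toy_site(rep(1L, 8), "AAAAAAAA", start = st, utr_len = 1000L)
    expect_lte(location_features(s, u)[["dist_ratio"]], 0.5)
    expect_gte(location_features(s, u)[["dist_ratio"]], 0)
  }
})

test_that("full site vectors: length, determinism, stable schema", {
  set.seed(64)
  m <- rand_mirna("m", 22)
  codes <- plant_rc_seed(sample.int(4L, 300, replace = TRUE), m$codes, 150L)
  u <- utr_seq("u", decode_rna(codes), cons = runif(300))
  sites <- scan_sites(m, u)
  expect_gte(length(sites), 1)
  v1 <- extract_site_features(sites[[1]], u, m)
  v2 <- extract_site_features(sites[[1]], u, m)
  expect_length(v1, 113)
  expect_identical(v1, v2)
  expect_equal(names(v1), site_feature_names())
  expect_false(anyDuplicated(site_feature_names()) > 0)
  # schema hash is stable across calls
  expect_identical(schema_hash(site_feature_names()),
                   schema_hash(site_feature_names()))
})

test_that("UTR features: empty case, single positive site, window maxima", {
  u <- utr_seq("u", rand_rna(500))
  f0 <- extract_utr_features(u, list(), numeric(0))
  expect_length(f0, 30)
  expect_equal(unname(f0["utr_length"]), 500)
  expect_equal(unname(f0["n_potential_sites"]), 0)
  expect_equal(unname(f0["top_score"]), score_floor())
  expect_true(all(f0[grep("^top_score_", names(f0))] == score_floor()))

  # one positive 8mer-A1 site scoring 1.2
  m <- mirna_seq("m", "UGGAAUGUAAAGAAGUAUGUAU")
  s <- toy_site(rep(1L, 8), "GCAUUCCA", start = 100L, utr_len = 500L)
  f1 <- extract_utr_features(u, list(s), 1.2)
  expect_equal(unname(f1["n_potential_8mer_A1"]), 1)
  expect_equal(unname(f1["n_positive_8mer_A1"]), 1)
  expect_equal(unname(f1["top_score_8mer_A1"]), 1.2)
  expect_equal(unname(f1["top_score"]), 1.2)
  expect_equal(unname(f1["n_positive_no_perfect_seed"]), 0)
  expect_equal(unname(f1["density_potential"]), 1 / 500)

  # window maxima equal brute force over all 100-nt windows
  set.seed(65)
  for (rep in 1:100) {
    L <- 400L
    n <- sample(0:12, 1)
    starts <- sort(sample(0:(L - 9), n))
    sites <- lapply(starts, function(st)
      toy_site(rep(3L, 8), "AAAAAAAA", start = st, utr_len = L))
    scores <- rnorm(n)
    ff <- extract_utr_features(utr_seq("w", strrep("A", L)), sites, scores)
    brute <- function(sel) {
      ss <- starts[sel]
      if (!length(ss)) return(0L)
      max(vapply(0:(L - 1), function(w) sum(ss >= w & ss < w + 100), 0L))
    }
    expect_equal(unname(ff["max100_potential"]), brute(rep(TRUE, n)))
    expect_equal(unname(ff["max100_positive"]), brute(scores > 0))
  }
})

test_that("counts are non-negative integers and densities exact", {
  set.seed(66)
  m <- rand_mirna("m", 22)
  u <- utr_seq("u", rand_rna(600))
  sites <- scan_sites(m, u)
  scores <- rnorm(length(sites))
  ff <- extract_utr_features(u, sites, scores)
  cnt <- ff[grep("^n_|^max100", names(ff))]
  expect_true(all(cnt >= 0 & cnt == round(cnt)))
  expect_equal(unname(ff["density_potential"]), length(sites) / 600)
  expect_equal(unname(ff["density_positive"]), sum(scores > 0) / 600)
})
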