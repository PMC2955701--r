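# Seed-match site filter.
#
# A candidate site is any UTR window whose seed alignment against miRNA
# positions p1..p8 satisfies at least one of five rules.  "W-C match" is a
# Watson-Crick pair, "match" additionally admits the G:U wobble.  Every
# "more than k" in the rules is read literally as >= k+1:
#   1. a run of >= 5 continuous W-C matches;
#   2. a run of >= 6 continuous matches and a run of >= 3 continuous W-C
#      matches;
#   3. >= 7 matches in total and a run of >= 4 continuous W-C matches, no gap;
#   4. p2, p3, p4 each W-C matched, >= 4 W-C matches and >= 5 matches in
#      total, no gap;
#   5. >= 6 matches and >= 6 W-C matches (strict reading; the looser >= 5 W-C
#      reading is available via `rule5_strict = FALSE`), at most one gap on
#      either strand.
# Rules 1-4 are evaluated on ungapped alignments; rule 5 additionally tries a
# single bulge at every position of either strand.

#' Summarise a seed-window alignment
#'
#' @param statuses integer alignment column statuses in miRNA 5'->3' order
#'   (1 WC, 2 GU, 3 mismatch, 4 gap). A UTR-side bulge appears as an extra
#'   gap column, so the vector has length 8 or 9.
#' @param mirna_index miRNA position of each column (NA for a UTR-side bulge
#'   column). Defaults to 1..length(statuses).
#' @return object of class `SeedAlignment` with the match counts and run
#'   lengths the filter rules consume.
#' @export
seed_alignment <- function(statuses, mirna_index = seq_along(statuses)) {
  statuses <- as.integer(statuses)
  gap_count <- sum(statuses == 4L)
  if (gap_count > 1L) stop("at most one gap is allowed in a seed alignment")
  is_wc <- statuses == 1L
  is_match <- statuses <= 2L
  max_run <- function(flag) {
    r <- rle(flag)
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  }
  structure(list(statuses = statuses, mirna_index = mirna_index,
                 gap_count = gap_count,
                 n_wc = sum(is_wc), n_match = sum(is_match),
                 run_wc = max_run(is_wc), run_match = max_run(is_match)),
            class = "SeedAlignment")
}

#' Evaluate the five seed-match filter rules
#'
#' @param align a `SeedAlignment`.
#' @param rule5_strict logical; TRUE (default) requires >= 6 matches and
#'   >= 6 W-C matches for rule 5, FALSE relaxes the W-C requirement to >= 5.
#' @return integer vector of satisfied rule ids (subset of 1:5), possibly
#'   empty.
#' @export
rule_check <- function(align, rule5_strict = TRUE) {
  stopifnot(inherits(align, "SeedAlignment"))
  out <- integer(0)
  if (align$gap_count == 0L) {
    p234_wc <- all(align$statuses[match(2:4, align$mirna_index)] == 1L)
    if (align$run_wc >= 5L) out <- c(out, 1L)
    if (align$run_match >= 6L && align$run_wc >= 3L) out <- c(out, 2L)
    if (align$n_match >= 7L && align$run_wc >= 4L) out <- c(out, 3L)
    if (p234_wc && align$n_wc >= 4L && align$n_match >= 5L) out <- c(out, 4L)
  }
  wc_need <- if (rule5_strict) 6L else 5L
  if (align$gap_count <= 1L && align$n_match >= 6L && align$n_wc >= wc_need)
    out <- c(out, 5L)
  out
}

# guarded status lookup: indices off the UTR count as mismatch
.stat_guard <- function(mcode, u, idx) {
  ok <- idx >= 1L & idx <= length(u)
  out <- rep(3L, length(idx))
  if (any(ok)) out[ok] <- pair_status_code(rep(mcode, sum(ok)), u[idx[ok]])
  out
}

#' Scan a 3'UTR for candidate miRNA binding sites
#'
#' Slides the seed window (step 1 nt) over the whole UTR, evaluates the five
#' filter rules at every position (rule 5 also with a single bulge on either
#' strand), and merges near-duplicate candidates whose seed intervals share
#' more than `merge_overlap` of the shorter interval, keeping the alignment
#' with more W-C matches.
#'
#' @param mirna a `MirnaSeq` (length >= 8).
#' @param utr a `UtrSeq`.
#' @param rule5_strict see [rule_check()].
#' @param merge_overlap overlap fraction (of the shorter site) above which two
#'   candidates are merged.
#' @param verbose log merges via `message()`.
#' @return list of `CandidateSite`, sorted 5'->3' by start; possibly empty.
#' @export
scan_sites <- function(mirna, utr, rule5_strict = TRUE, merge_overlap = 0.5,
                       verbose = FALSE) {
  stopifnot(inherits(mirna, "MirnaSeq"), inherits(utr, "UtrSeq"))
  if (mirna$M < 8) stop("miRNA shorter than the 8-nt seed window")
  L <- utr$length
  if (L < 8) return(list())
  m <- mirna$codes[1:8]
  u <- utr$codes
  qi <- 8:L                       # 1-based coordinate of q1
  K <- length(qi)

  S0 <- S1 <- S2 <- matrix(3L, K, 8)
  for (mm in 1:8) {
    S0[, mm] <- .stat_guard(m[mm], u, qi - mm + 1L)
    S1[, mm] <- .stat_guard(m[mm], u, qi - mm + 2L)  # after a miRNA bulge
    S2[, mm] <- .stat_guard(m[mm], u, qi - mm)       # after a UTR bulge
  }
  wc0 <- S0 == 1L; mt0 <- S0 <= 2L
  n_wc <- rowSums(wc0); n_match <- rowSums(mt0)
  run_wc <- run_match <- cw <- cm <- rep(0L, K)
  for (mm in 1:8) {
    cw <- ifelse(wc0[, mm], cw + 1L, 0L); run_wc <- pmax(run_wc, cw)
    cm <- ifelse(mt0[, mm], cm + 1L, 0L); run_match <- pmax(run_match, cm)
  }
  wc_need <- if (rule5_strict) 6L else 5L
  r1 <- run_wc >= 5L
  r2 <- run_match >= 6L & run_wc >= 3L
  r3 <- n_match >= 7L & run_wc >= 4L
  r4 <- S0[, 2] == 1L & S0[, 3] == 1L & S0[, 4] == 1L &
    n_wc >= 4L & n_match >= 5L
  r5u <- n_match >= 6L & n_wc >= wc_need

  # single-gap alignments for rule 5: prefix of S0 + shifted suffix
  cum0w <- t(apply(wc0, 1, cumsum)); cum0m <- t(apply(mt0, 1, cumsum))
  sufsum <- function(S, val) {
    X <- matrix(0L, K, 9)
    for (mm in 8:1) X[, mm] <- X[, mm + 1] + (S[, mm] <= val)
    X
  }
  suf1w <- sufsum(S1, 1L); suf1m <- sufsum(S1, 2L)
  suf2w <- sufsum(S2, 1L); suf2m <- sufsum(S2, 2L)
  pre_w <- cbind(0L, cum0w); pre_m <- cbind(0L, cum0m)  # col g+1 = sum 1..g

  best_gap <- data.frame(k = integer(0))
  gap_pass <- rep(FALSE, K)
  gap_wc <- gap_mt <- rep(-1L, K)
  gap_g <- gap_side <- rep(0L, K)
  for (g in 2:7) {               # miRNA bulge at p_g (interior only)
    w <- pre_w[, g] + suf1w[, g + 1]
    mt <- pre_m[, g] + suf1m[, g + 1]
    hit <- mt >= 6L & w >= wc_need
    upd <- hit & (w > gap_wc | (w == gap_wc & mt > gap_mt))
    gap_wc[upd] <- w[upd]; gap_mt[upd] <- mt[upd]
    gap_g[upd] <- g; gap_side[upd] <- 1L
    gap_pass <- gap_pass | hit
  }
  for (g in 1:7) {               # UTR-side bulge between q_g and q_{g+1}
    w <- pre_w[, g + 1] + suf2w[, g + 1]
    mt <- pre_m[, g + 1] + suf2m[, g + 1]
    hit <- mt >= 6L & w >= wc_need
    upd <- hit & (w > gap_wc | (w == gap_wc & mt > gap_mt))
    gap_wc[upd] <- w[upd]; gap_mt[upd] <- mt[upd]
    gap_g[upd] <- g; gap_side[upd] <- 2L
    gap_pass <- gap_pass | hit
  }

  ungapped <- r1 | r2 | r3 | r4 | r5u
  hits <- which(ungapped | gap_pass)
  if (!length(hits)) return(list())

  cand <- vector("list", length(hits))
  for (idx in seq_along(hits)) {
    k <- hits[idx]
    i <- qi[k]
    if (ungapped[k]) {
      rule <- which(c(r1[k], r2[k], r3[k], r4[k], r5u[k]))[1]
      cand[[idx]] <- list(start = i - 8L, end = i, rule = rule,
                          statuses = S0[k, ], mirna_index = 1:8,
                          n_wc = n_wc[k], n_match = n_match[k], gap = 0L)
    } else {
      g <- gap_g[k]
      if (gap_side[k] == 1L) {   # miRNA bulge: 7 site nts, gap at p_g
        st <- c(if (g > 1) S0[k, 1:(g - 1)], 4L, S1[k, (g + 1):8])
        mi <- 1:8
        cand[[idx]] <- list(start = i - 7L, end = i, rule = 5L,
                            statuses = st, mirna_index = mi,
                            n_wc = gap_wc[k], n_match = gap_mt[k], gap = 1L)
      } else {                   # UTR bulge: 9 site nts, extra gap column
        st <- c(S0[k, 1:g], 4L, S2[k, (g + 1):8])
        mi <- c(1:g, NA, (g + 1):8)
        cand[[idx]] <- list(start = i - 9L, end = i, rule = 5L,
                            statuses = st, mirna_index = mi,
                            n_wc = gap_wc[k], n_match = gap_mt[k], gap = 1L)
      }
    }
  }
  # clip candidates whose gapped window ran off the UTR 5' end
  cand <- Filter(function(s) s$start >= 0L, cand)
  if (!length(cand)) return(list())
  cand <- cand[order(vapply(cand, `[[`, 0L, "start"))]

  better <- function(a, b) {     # TRUE if a should win the merge
    if (a$n_wc != b$n_wc) return(a$n_wc > b$n_wc)
    if (a$n_match != b$n_match) return(a$n_match > b$n_match)
    if (a$start != b$start) return(a$start < b$start)
    a$rule <= b$rule
  }
  kept <- list()
  cur <- cand[[1]]
  for (s in cand[-1]) {
    ov <- min(cur$end, s$end) - max(cur$start, s$start)
    shorter <- min(cur$end - cur$start, s$end - s$start)
    if (ov > merge_overlap * shorter) {
      win <- if (better(cur, s)) cur else s
      if (verbose)
        message("merged overlapping candidates at [", cur$start, ",", cur$end,
                ") and [", s$start, ",", s$end, ") keeping start ", win$start)
      cur <- win
    } else {
      kept[[length(kept) + 1]] <- cur
      cur <- s
    }
  }
  kept[[length(kept) + 1]] <- cur

  lapply(kept, function(s)
    candidate_site(utr_id = utr$id, mirna_id = mirna$id,
                   start = s$start, end = s$end, rule_id = s$rule,
                   statuses = s$statuses, mirna_index = s$mirna_index,
                   n_wc = s$n_wc, n_match = s$n_match, gap_count = s$gap,
                   seed_string = substr(utr$seq, s$start + 1, s$end),
                   utr_length = L))
}

#' Write candidate sites as a TSV
#'
#' @param sites list of `CandidateSite`.
#' @param path output file.
#' @export
write_sites <- function(sites, path) {
  df <- sites_to_df(sites)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flatten candidate sites to a data.frame
#'
#' @param sites list of `CandidateSite`.
#' @return data.frame with columns utr_id, mirna_id, start, end, rule_id,
#'   n_wc, n_match, seed_string.
#' @export
sites_to_df <- function(sites) {
  if (!length(sites))
    return(data.frame(utr_id = character(0), mirna_id = character(0),
                      start = integer(0), end = integer(0),
                      rule_id = integer(0), n_wc = integer(0),
                      n_match = integer(0), seed_string = character(0)))
  data.frame(utr_id = vapply(sites, `[[`, "", "utr_id"),
             mirna_id = vapply(sites, `[[`, "", "mirna_id"),
             start = vapply(sites, `[[`, 0L, "start"),
             end = vapply(sites, `[[`, 0L, "end"),
             rule_id = vapply(sites, `[[`, 0L, "rule_id"),
             n_wc = vapply(sites, `[[`, 0L, "n_wc"),
             n_match = vapply(sites, `[[`, 0L, "n_match"),
             seed_string = vapply(sites, `[[`, "", "seed_string"),
             stringsAsFactors = FALSE)
}
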