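# Training-corpus construction: positives from a miRecords-like table,
# negatives from over-expression differential-expression tables, and a
# synthetic corpus generator with known ground truth.

#' Criteria for deriving negative targets from expression data
#'
#' Negative targets are the most confidently up-regulated genes under miRNA
#' over-expression: small p value, fold change at or above a floor, and
#' consistent direction across timepoints when timepoint columns exist.
#'
#' @param p_value ceiling on the differential-expression p value.
#' @param fold_change floor on the linear up-regulation fold change.
#' @param consistency minimum fraction of timepoints with positive change.
#' @return list of class `NegativeCriteria`.
#' @export
negative_criteria <- function(p_value = 0.01, fold_change = 1.5,
                              consistency = 2 / 3) {
  stopifnot(p_value > 0, p_value <= 1, fold_change >= 1,
            consistency >= 0, consistency <= 1)
  structure(list(p_value = p_value, fold_change = fold_change,
                 consistency = consistency),
            class = "NegativeCriteria")
}

# locate a site string in a UTR by exact match; NA start = not found,
# -1 = ambiguous (multiple hits)
.locate_site <- function(site_seq, utr) {
  site_seq <- normalize_rna(site_seq)
  hits <- gregexpr(site_seq, utr$seq, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(NA_integer_)
  if (length(hits) > 1) return(-1L)
  hits[1] - 1L                               # 0-based
}

# build a CandidateSite for a known site interval by aligning the seed
# window ungapped at the site's 3' end; rule_id = lowest satisfied rule, or
# 5 if the validated site escapes every rule (logged by the caller)
.site_from_interval <- function(mirna, utr, start, end) {
  st <- pair_status_code(mirna$codes[1:8], utr$codes[end - (1:8) + 1L])
  al <- seed_alignment(st)
  rules <- rule_check(al)
  candidate_site(utr$id, mirna$id, max(end - 8L, start), end,
                 rule_id = if (length(rules)) min(rules) else 5L,
                 statuses = st, mirna_index = 1:8,
                 n_wc = al$n_wc, n_match = al$n_match,
                 seed_string = substr(utr$seq, max(end - 8L, start) + 1, end),
                 utr_length = utr$length)
}

#' Build positive training pairs from a miRecords-like table
#'
#' Site sequences are located in their UTR by exact substring match;
#' records whose site is absent or ambiguous (multiple hits) are dropped
#' with a logged reason. Duplicate (mirna, utr, interval) records collapse
#' to one. Records without site information contribute UTR-level positives
#' only.
#'
#' @param records data.frame with columns `mirna_id`, `utr_id` and optional
#'   `site_seq`.
#' @param utrs named list of `UtrSeq`.
#' @param mirnas named list of `MirnaSeq`.
#' @return data.frame of labeled pairs (mirna_id, utr_id, label, level,
#'   start, end).
#' @export
build_positives <- function(records, utrs, mirnas) {
  rows <- list()
  seen_sites <- character(0)
  seen_utr <- character(0)
  for (i in seq_len(nrow(records))) {
    mid <- records$mirna_id[i]; uid <- records$utr_id[i]
    if (!mid %in% names(mirnas) || !uid %in% names(utrs)) {
      message("skipping record ", i, ": unmapped id ", mid, "/", uid)
      next
    }
    site_seq <- if ("site_seq" %in% names(records)) records$site_seq[i] else NA
    if (!is.na(site_seq) && nzchar(site_seq)) {
      pos <- .locate_site(site_seq, utrs[[uid]])
      if (is.na(pos)) {
        message("dropping record ", i, ": site not found in ", uid)
        next
      }
      if (pos < 0) {
        message("dropping record ", i, ": ambiguous site in ", uid)
        next
      }
      start <- pos; end <- pos + nchar(site_seq)
      key <- paste(mid, uid, start, end)
      if (!key %in% seen_sites) {
        seen_sites <- c(seen_sites, key)
        rows[[length(rows) + 1]] <-
          data.frame(mirna_id = mid, utr_id = uid, label = "positive",
                     level = "site", start = start, end = end,
                     stringsAsFactors = FALSE)
      }
    }
    ukey <- paste(mid, uid)
    if (!ukey %in% seen_utr) {
      seen_utr <- c(seen_utr, ukey)
      rows[[length(rows) + 1]] <-
        data.frame(mirna_id = mid, utr_id = uid, label = "positive",
                   level = "utr", start = NA_integer_, end = NA_integer_,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(data.frame())))
  message(sum(out$level == "site"), " site-level and ",
          sum(out$level == "utr"), " utr-level positives built")
  out
}

#' Derive negative training pairs from an expression table
#'
#' Genes passing all [negative_criteria()] become negative UTR-level pairs;
#' their filter candidate sites become negative site-level pairs.
#'
#' @param expression_rows data.frame from [read_expression_table()]; any
#'   numeric columns beyond the canonical three are treated as per-timepoint
#'   log fold changes.
#' @param criteria a `NegativeCriteria`.
#' @param mirna the over-expressed `MirnaSeq`.
#' @param utrs named list of `UtrSeq` (matched on `gene`, falling back to
#'   id).
#' @return data.frame of labeled pairs, as [build_positives()].
#' @export
build_negatives <- function(expression_rows, criteria, mirna, utrs) {
  stopifnot(inherits(criteria, "NegativeCriteria"))
  tp_cols <- setdiff(names(expression_rows),
                     c("gene", "log_fold_change", "p_value"))
  tp_cols <- tp_cols[vapply(expression_rows[tp_cols], is.numeric, TRUE)]
  pass <- expression_rows$p_value <= criteria$p_value &
    2^expression_rows$log_fold_change >= criteria$fold_change &
    expression_rows$log_fold_change > 0
  if (length(tp_cols)) {
    cons_frac <- rowMeans(as.matrix(expression_rows[tp_cols]) > 0)
    pass <- pass & cons_frac >= criteria$consistency
  }
  genes <- expression_rows$gene[pass]
  if (!length(genes)) warning("no gene passes the negative criteria")
  gene_of <- vapply(utrs, function(u) u$gene, "")
  rows <- list()
  for (g in genes) {
    uid <- names(utrs)[match(g, gene_of)]
    if (is.na(uid)) uid <- if (g %in% names(utrs)) g else NA
    if (is.na(uid)) {
      message("negative gene ", g, " has no UTR record; skipped")
      next
    }
    rows[[length(rows) + 1]] <-
      data.frame(mirna_id = mirna$id, utr_id = uid, label = "negative",
                 level = "utr", start = NA_integer_, end = NA_integer_,
                 stringsAsFactors = FALSE)
    for (s in scan_sites(mirna, utrs[[uid]])) {
      rows[[length(rows) + 1]] <-
        data.frame(mirna_id = mirna$id, utr_id = uid, label = "negative",
                   level = "site", start = s$start, end = s$end,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(data.frame())))
  message(sum(out$level == "utr"), " negative UTR pair(s), ",
          sum(out$level == "site"), " negative site pair(s)")
  out
}

# ---------------------------------------------------------------------------
# Synthetic corpus

#' Specification of a synthetic corpus
#'
#' Defaults state the emulated world: a handful of 22-nt miRNAs, positive
#' UTRs carrying 1-3 planted sites drawn from a rule mix dominated by
#' perfect seed matches, elevated conservation and AU-rich context at
#' planted sites plus partial 3' pairing (p13..p18), and negative UTRs
#' scrubbed free of any rule-satisfying window by rejection sampling.
#'
#' @param n_mirnas number of miRNAs.
#' @param mirna_length miRNA length in nt.
#' @param n_pos_utrs,n_neg_utrs positive/negative UTRs per miRNA.
#' @param utr_len_range UTR length range (uniform).
#' @param sites_per_pos possible planted-site counts per positive UTR.
#' @param rule_mix sampling weights for planted rule types 1..5.
#' @param cons_site,cons_bg conservation ranges at planted sites /
#'   background.
#' @param au_context probability of A or U per context nucleotide.
#' @param q1_A_prob probability that a planted site has an A opposite p1.
#' @param three_prime_pair plant complementary pairing at p13..p18.
#' @param seed RNG seed recorded in the manifest.
#' @return list of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_mirnas = 2L, mirna_length = 22L,
                           n_pos_utrs = 40L, n_neg_utrs = 40L,
                           utr_len_range = c(400L, 900L),
                           sites_per_pos = 1:3,
                           rule_mix = c(0.5, 0.2, 0.15, 0.1, 0.05),
                           cons_site = c(0.75, 0.95),
                           cons_bg = c(0, 0.3),
                           au_context = 0.75, q1_A_prob = 0.5,
                           three_prime_pair = TRUE, seed = 1L) {
  stopifnot(n_mirnas >= 1, n_pos_utrs >= 0, n_neg_utrs >= 0,
            length(rule_mix) == 5, all(rule_mix >= 0))
  structure(list(n_mirnas = n_mirnas, mirna_length = mirna_length,
                 n_pos_utrs = n_pos_utrs, n_neg_utrs = n_neg_utrs,
                 utr_len_range = utr_len_range,
                 sites_per_pos = sites_per_pos, rule_mix = rule_mix,
                 cons_site = cons_site, cons_bg = cons_bg,
                 au_context = au_context, q1_A_prob = q1_A_prob,
                 three_prime_pair = three_prime_pair,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

.COMPLEMENT <- c(4L, 3L, 2L, 1L)     # A<->U, C<->G

# a code that is neither WC nor GU against miRNA code a
.mismatch_code <- function(a) {
  ok <- which(pair_status_code(rep(a, 4), 1:4) == 3L)
  ok[sample.int(length(ok), 1)]
}

# plant one site with q1 at 0-based coordinate c; returns modified codes and
# the seed interval
.plant_site <- function(codes, m, c, rule, q1A) {
  end <- c + 1L
  set_q <- function(codes, k, val) { codes[end - k + 1L] <- val; codes }
  wc <- function(k) .COMPLEMENT[m[k]]
  # match = WC or GU; prefer GU where the miRNA nt admits one
  gu <- function(k) if (m[k] == 3L) 4L else if (m[k] == 4L) 3L else wc(k)
  if (rule == 1L) {
    for (k in 1:8) codes <- set_q(codes, k, wc(k))
    start <- end - 8L
  } else if (rule == 2L) {
    for (k in 1:8) codes <- set_q(codes, k, if (k %in% 3:5) wc(k) else gu(k))
    start <- end - 8L
  } else if (rule == 3L) {
    for (k in 1:7) codes <- set_q(codes, k, if (k <= 4) wc(k) else gu(k))
    codes <- set_q(codes, 8, .mismatch_code(m[8]))
    start <- end - 8L
  } else if (rule == 4L) {
    for (k in 1:8) codes <- set_q(codes, k, .mismatch_code(m[k]))
    for (k in c(2:4, 6)) codes <- set_q(codes, k, wc(k))
    codes <- set_q(codes, 8, gu(8))
    start <- end - 8L
  } else {
    # rule 5: full WC with one extra UTR nt bulged between q4 and q5
    for (k in 1:4) codes <- set_q(codes, k, wc(k))
    codes[end - 5L + 1L] <- sample.int(4L, 1)          # bulged nt
    for (k in 5:8) codes[end - k] <- .COMPLEMENT[m[k]] # shifted by one
    start <- end - 9L
  }
  if (q1A && pair_status_code(m[1], 1L) == 3L)
    codes <- set_q(codes, 1, 1L)     # literal A opposite p1 (unpaired)
  list(codes = codes, start = start, end = end)
}

#' Generate a synthetic corpus with known ground truth
#'
#' Positive UTRs carry planted sites satisfying a sampled filter rule by
#' construction, with AU-enriched context, optional 3' pairing at p13..p18
#' and elevated conservation; negative UTRs are re-randomized until the
#' filter finds no candidate site (rejection sampling). The manifest records
#' the seed and every planted locus.
#'
#' @param spec a `SyntheticSpec`.
#' @return list of class `SyntheticCorpus` with `mirnas`, `utrs` (both named
#'   lists), `pairs` (labeled-pair data.frame) and `manifest`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  mirnas <- list()
  utrs <- list()
  pairs <- list()
  planted <- list()

  for (mi in seq_len(spec$n_mirnas)) {
    mid <- sprintf("mir%02d", mi)
    mcod <- sample.int(4L, spec$mirna_length, replace = TRUE)
    mirnas[[mid]] <- mirna_seq(mid, decode_rna(mcod))
    m <- mcod

    for (ui in seq_len(spec$n_pos_utrs)) {
      uid <- sprintf("%s_pos%03d", mid, ui)
      L <- sample(spec$utr_len_range[1]:spec$utr_len_range[2], 1)
      codes <- sample.int(4L, L, replace = TRUE)
      cons <- stats::runif(L, spec$cons_bg[1], spec$cons_bg[2])
      k_sites <- sample(spec$sites_per_pos, 1)
      # spaced loci, clear of both UTR ends
      lo <- 40L; hi <- L - 15L
      loci <- integer(0)
      for (tries in 1:200) {
        cand <- sample(lo:hi, 1)
        if (all(abs(cand - loci) >= 60L)) loci <- c(loci, cand)
        if (length(loci) == k_sites) break
      }
      for (c0 in loci) {
        rule <- sample.int(5L, 1, prob = spec$rule_mix)
        # AU-rich context around the future site
        ctx <- c((c0 - 18L):(c0 - 9L), (c0 + 1L):(c0 + 10L))
        ctx <- ctx[ctx >= 0 & ctx < L]
        au <- stats::runif(length(ctx)) < spec$au_context
        codes[ctx + 1L][au] <- sample(c(1L, 4L), sum(au), replace = TRUE)
        pl <- .plant_site(codes, m, c0, rule,
                          q1A = stats::runif(1) < spec$q1_A_prob)
        codes <- pl$codes
        if (spec$three_prime_pair) {
          for (mm in 13:18) {
            cc <- pl$start - (mm - 8L)
            if (cc >= 0) codes[cc + 1L] <- .COMPLEMENT[m[mm]]
          }
        }
        span <- max(0L, pl$start - 10L):min(L - 1L, pl$end + 9L)
        cons[span + 1L] <- stats::runif(length(span), spec$cons_site[1],
                                        spec$cons_site[2])
        planted[[length(planted) + 1]] <-
          data.frame(mirna_id = mid, utr_id = uid, start = pl$start,
                     end = pl$end, rule = rule, stringsAsFactors = FALSE)
        pairs[[length(pairs) + 1]] <-
          data.frame(mirna_id = mid, utr_id = uid, label = "positive",
                     level = "site", start = pl$start, end = pl$end,
                     stringsAsFactors = FALSE)
      }
      utrs[[uid]] <- utr_seq(uid, decode_rna(codes), cons = cons)
      pairs[[length(pairs) + 1]] <-
        data.frame(mirna_id = mid, utr_id = uid, label = "positive",
                   level = "utr", start = NA_integer_, end = NA_integer_,
                   stringsAsFactors = FALSE)
    }

    for (ui in seq_len(spec$n_neg_utrs)) {
      uid <- sprintf("%s_neg%03d", mid, ui)
      L <- sample(spec$utr_len_range[1]:spec$utr_len_range[2], 1)
      codes <- sample.int(4L, L, replace = TRUE)
      u <- utr_seq(uid, decode_rna(codes))
      for (iter in 1:60) {
        hits <- scan_sites(mirnas[[mid]], u)
        if (!length(hits)) break
        for (s in hits) {
          span <- max(0L, s$start - 1L):min(L - 1L, s$end)
          codes[span + 1L] <- sample.int(4L, length(span), replace = TRUE)
        }
        u <- utr_seq(uid, decode_rna(codes))
        if (iter == 60L) stop("failed to scrub negative UTR ", uid)
      }
      cons <- stats::runif(L, spec$cons_bg[1], spec$cons_bg[2])
      utrs[[uid]] <- utr_seq(uid, decode_rna(codes), cons = cons)
      pairs[[length(pairs) + 1]] <-
        data.frame(mirna_id = mid, utr_id = uid, label = "negative",
                   level = "utr", start = NA_integer_, end = NA_integer_,
                   stringsAsFactors = FALSE)
    }
  }

  pairs <- do.call(rbind, pairs)
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(mirna_id = character(0), utr_id = character(0),
               start = integer(0), end = integer(0), rule = integer(0))
  structure(list(mirnas = mirnas, utrs = utrs, pairs = pairs,
                 manifest = list(seed = spec$seed, spec = unclass(spec),
                                 planted = planted)),
            class = "SyntheticCorpus")
}

#' @export
print.SyntheticCorpus <- function(x, ...) {
  cat("<SyntheticCorpus> ", length(x$mirnas), " miRNA(s), ",
      length(x$utrs), " UTR(s), ", nrow(x$manifest$planted),
      " planted site(s)\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Dataset assembly for the two-stage learner

#' Scan and featurize every (miRNA, UTR) pair of a corpus
#'
#' One pass computing candidate sites and their 113-feature vectors; reused
#' by both stage datasets.
#'
#' @param corpus a `SyntheticCorpus` (or a list with the same shape).
#' @param params energy parameters.
#' @param window_pad accessibility pad.
#' @return nested list: `scan[[mirna_id]][[utr_id]]` = list(sites, X,
#'   positive) where `positive` flags sites overlapping a site-level
#'   positive by at least half the labeled interval.
#' @export
corpus_scan <- function(corpus, params = default_energy_params(),
                        window_pad = 70) {
  out <- list()
  upairs <- corpus$pairs[corpus$pairs$level == "utr", ]
  spairs <- corpus$pairs[corpus$pairs$level == "site" &
                           corpus$pairs$label == "positive", ]
  for (mid in unique(upairs$mirna_id)) {
    mirna <- corpus$mirnas[[mid]]
    out[[mid]] <- list()
    for (uid in upairs$utr_id[upairs$mirna_id == mid]) {
      u <- corpus$utrs[[uid]]
      sites <- scan_sites(mirna, u)
      truth <- spairs[spairs$mirna_id == mid & spairs$utr_id == uid, ]
      if (length(sites)) {
        X <- t(vapply(sites, function(s)
          extract_site_features(s, u, mirna, params = params,
                                window_pad = window_pad), numeric(113)))
        colnames(X) <- site_feature_names()
        positive <- vapply(sites, function(s) {
          if (!nrow(truth)) return(FALSE)
          ov <- pmin(s$end, truth$end) - pmax(s$start, truth$start)
          any(ov >= (truth$end - truth$start) / 2)
        }, TRUE)
      } else {
        X <- matrix(numeric(0), 0, 113,
                    dimnames = list(NULL, site_feature_names()))
        positive <- logical(0)
      }
      out[[mid]][[uid]] <- list(sites = sites, X = X, positive = positive)
    }
  }
  out
}

#' Assemble the site-level training dataset
#'
#' Positive examples are candidate sites overlapping a labeled positive
#' site; all other candidate sites are negatives, optionally subsampled to
#' `config$max_neg_sites` (seeded).
#'
#' @param corpus a corpus.
#' @param scan optional precomputed [corpus_scan()] result.
#' @param config a `TrainConfig`.
#' @inheritParams corpus_scan
#' @return list(X, y, meta) with X 113 columns.
#' @export
build_site_dataset <- function(corpus, scan = NULL, config = train_config(),
                               params = default_energy_params(),
                               window_pad = 70) {
  if (is.null(scan)) scan <- corpus_scan(corpus, params, window_pad)
  Xs <- list(); ys <- list(); meta <- list()
  for (mid in names(scan)) for (uid in names(scan[[mid]])) {
    e <- scan[[mid]][[uid]]
    if (!nrow(e$X)) next
    Xs[[length(Xs) + 1]] <- e$X
    ys[[length(ys) + 1]] <- as.integer(e$positive)
    meta[[length(meta) + 1]] <-
      data.frame(mirna_id = mid, utr_id = uid,
                 start = vapply(e$sites, function(s) s$start, 0L),
                 stringsAsFactors = FALSE)
  }
  X <- do.call(rbind, Xs); y <- unlist(ys); meta <- do.call(rbind, meta)
  neg <- which(y == 0)
  if (length(neg) > config$max_neg_sites) {
    set.seed(config$seed)
    keep <- sort(c(which(y == 1), sample(neg, config$max_neg_sites)))
    X <- X[keep, , drop = FALSE]; y <- y[keep]; meta <- meta[keep, ]
  }
  message("site dataset: ", sum(y == 1), " positive / ", sum(y == 0),
          " negative site(s)")
  list(X = X, y = y, meta = meta)
}

#' Assemble the UTR-level training dataset
#'
#' @param corpus a corpus.
#' @param site_model trained site-stage `StageModel` providing site scores.
#' @param scan optional precomputed [corpus_scan()] result.
#' @inheritParams corpus_scan
#' @return list(X, y, meta) with X 30 columns.
#' @export
build_utr_dataset <- function(corpus, site_model, scan = NULL,
                              params = default_energy_params(),
                              window_pad = 70) {
  if (is.null(scan)) scan <- corpus_scan(corpus, params, window_pad)
  upairs <- corpus$pairs[corpus$pairs$level == "utr", ]
  Xs <- list(); ys <- integer(0); meta <- list()
  for (i in seq_len(nrow(upairs))) {
    mid <- upairs$mirna_id[i]; uid <- upairs$utr_id[i]
    e <- scan[[mid]][[uid]]
    scores <- if (nrow(e$X)) predict_stage(site_model, e$X) else numeric(0)
    Xs[[length(Xs) + 1]] <-
      extract_utr_features(corpus$utrs[[uid]], e$sites, scores)
    ys <- c(ys, as.integer(upairs$label[i] == "positive"))
    meta[[length(meta) + 1]] <-
      data.frame(mirna_id = mid, utr_id = uid, stringsAsFactors = FALSE)
  }
  X <- do.call(rbind, Xs)
  colnames(X) <- utr_feature_names()
  list(X = X, y = ys, meta = do.call(rbind, meta))
}

#' Train both SVM stages on a corpus
#'
#' @param corpus a corpus with labeled pairs.
#' @param config a `TrainConfig`.
#' @inheritParams corpus_scan
#' @return list of class `TwoStageModel`: `site_model`, `utr_model`,
#'   `config`.
#' @export
train_two_stage <- function(corpus, config = train_config(),
                            params = default_energy_params(),
                            window_pad = 70) {
  scan <- corpus_scan(corpus, params, window_pad)
  sd <- build_site_dataset(corpus, scan, config, params, window_pad)
  site_model <- train_stage(sd$X, sd$y, config, "site")
  ud <- build_utr_dataset(corpus, site_model, scan, params, window_pad)
  utr_model <- train_stage(ud$X, ud$y, config, "utr")
  structure(list(site_model = site_model, utr_model = utr_model,
                 config = config),
            class = "TwoStageModel")
}

#' Split a corpus into train and held-out parts at the UTR level
#'
#' Stratified by miRNA and label; site-level pairs follow their UTR.
#'
#' @param corpus a corpus.
#' @param frac fraction of UTRs kept for training.
#' @param seed RNG seed.
#' @return list(train, test) of corpora.
#' @export
split_corpus <- function(corpus, frac = 0.75, seed = 1L) {
  up <- corpus$pairs[corpus$pairs$level == "utr", ]
  set.seed(seed)
  train_ids <- character(0)
  for (mid in unique(up$mirna_id)) for (lab in unique(up$label)) {
    ids <- up$utr_id[up$mirna_id == mid & up$label == lab]
    train_ids <- c(train_ids, sample(ids, round(frac * length(ids))))
  }
  subset_corpus <- function(keep) {
    p <- corpus$pairs[corpus$pairs$utr_id %in% keep, ]
    structure(list(mirnas = corpus$mirnas,
                   utrs = corpus$utrs[unique(p$utr_id)],
                   pairs = p, manifest = corpus$manifest),
              class = "SyntheticCorpus")
  }
  list(train = subset_corpus(train_ids),
       test = subset_corpus(setdiff(up$utr_id, train_ids)))
}
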