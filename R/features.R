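# Feature extraction: 113 site features in 7 groups and 30 UTR features in
# 3 groups, as named, ordered numeric vectors.
#
# Group sizes: seed match 6, pair-wise structure 39 (20 statuses + 19 miRNA
# 2-mer codes), regional structure 18, conservation 3, energy 4, seed
# context 40 (4 + 16 pooled composition counts + 20 positional codes),
# location 3.  UTR: length 1, density 4, site-score 25 (7 seed categories x
# 3 + 4 globals).  Sentinel for an empty category's top score is
# `score_floor()`; positions that fall off a UTR end are coded 0 ("absent")
# and excluded from composition counts.

#' Sentinel score for empty categories / siteless UTRs
#' @return the large negative constant used as a score floor.
#' @export
score_floor <- function() -999

.SEED_TYPES <- c("6mer", "7mer_A1", "7mer_m1", "7mer_m8", "8mer_A1",
                 "8mer_m8")
# UTR-level category names keep the "8mer_m1" alias used for the 8mer-m8
# site type in the optimal-feature tables
.UTR_CATEGORIES <- c("6mer", "7mer_A1", "7mer_m1", "7mer_m8", "8mer_A1",
                     "8mer_m1", "no_perfect_seed")

#' Canonical site feature names (length 113)
#' @return character vector of the 113 site feature names, in extraction
#'   order.
#' @export
site_feature_names <- function() {
  dimers <- as.vector(t(outer(.NT_CHARS, .NT_CHARS, paste0)))
  c(paste0("seed_", .SEED_TYPES),
    paste0("status_p", 1:20),
    paste0("dimer_p", 1:19),
    paste0("n_", rep(c("wc", "gu", "mismatch", "gap"), 3), "_",
           rep(c("seed", "three", "total"), each = 4)),
    paste0("bulge_", rep(c("count", "nt"), 3), "_",
           rep(c("seed", "three", "total"), each = 2)),
    c("cons_seed", "cons_context5", "cons_context3"),
    c("e_seed", "e_three", "e_total", "ddg"),
    paste0("comp_", c(.NT_CHARS, dimers)),
    paste0("pos_r", 1:10), paste0("pos_q", 0:-9),
    c("dist_stop", "dist_nearest_end", "dist_ratio"))
}

#' Canonical UTR feature names (length 30)
#' @return character vector of the 30 UTR feature names, in extraction order.
#' @export
utr_feature_names <- function() {
  c("utr_length",
    "density_potential", "density_positive",
    "max100_potential", "max100_positive",
    as.vector(t(outer(.UTR_CATEGORIES,
                      c("n_potential", "n_positive", "top_score"),
                      function(a, b) paste0(b, "_", a)))),
    "top_score", "total_positive_score", "n_positive_sites",
    "n_potential_sites")
}

#' Stable hash of a feature schema
#'
#' @param names character vector of feature names.
#' @return md5 hex string of the collapsed schema.
#' @export
schema_hash <- function(names) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names, collapse = "\x1f"), f)
  unname(tools::md5sum(f))
}

# WC status of a site's seed alignment at miRNA positions `ps` (all TRUE iff
# each position is a Watson-Crick pair; a gap column anywhere inside the
# spanned range breaks the perfect match)
.seed_wc_range <- function(site, a, b) {
  idx <- match(a:b, site$mirna_index)
  if (anyNA(idx)) return(FALSE)
  if (!all(site$statuses[idx] == 1L)) return(FALSE)
  # a UTR-side bulge column between the matched positions breaks contiguity
  gapcols <- which(is.na(site$mirna_index))
  !length(gapcols) || all(gapcols < min(idx) | gapcols > max(idx))
}

#' Perfect seed match features (6 booleans)
#'
#' Types: 6mer (p2~p7 WC), 7mer-A1 (p2~p7 WC and q1 is A), 7mer-m1 (p1~p7
#' WC), 7mer-m8 (p2~p8 WC), 8mer-A1 (p2~p8 WC and q1 is A), 8mer-m8 (p1~p8
#' WC). The A1 variants test the literal identity of the UTR nucleotide
#' opposite p1, not a pair.
#'
#' @param site a `CandidateSite`.
#' @return named 0/1 vector of length 6.
#' @export
seed_match_features <- function(site) {
  q1 <- substr(site$seed_string, nchar(site$seed_string),
               nchar(site$seed_string))
  wc27 <- .seed_wc_range(site, 2, 7)
  wc17 <- .seed_wc_range(site, 1, 7)
  wc28 <- .seed_wc_range(site, 2, 8)
  wc18 <- .seed_wc_range(site, 1, 8)
  out <- as.numeric(c(wc27,
                      wc27 && q1 == "A",
                      wc17,
                      wc28,
                      wc28 && q1 == "A",
                      wc18))
  names(out) <- paste0("seed_", .SEED_TYPES)
  out
}

#' Pair-wise binding structure features (39 values)
#'
#' Match status (1..4) of miRNA positions p1..p20 and the miRNA 2-mer
#' content code (1..16) at p1..p19. Positions beyond the miRNA length are
#' coded 0.
#'
#' @param duplex a `DuplexStructure`.
#' @return named numeric vector of length 39.
#' @export
pairwise_features <- function(duplex) {
  st <- rep(0L, 20); st[seq_along(duplex$status)] <- duplex$status
  dm <- rep(0L, 19); dm[seq_along(duplex$dimer_code)] <- duplex$dimer_code
  out <- as.numeric(c(st, dm))
  names(out) <- c(paste0("status_p", 1:20), paste0("dimer_p", 1:19))
  out
}

#' Regional binding structure features (18 values)
#'
#' W-C / G:U / mismatch / gap counts for the seed (p1..p8), 3' (p9..p20) and
#' total regions, plus the mRNA-side bulge count and bulged nucleotide count
#' per region.
#'
#' @param duplex a `DuplexStructure`.
#' @return named numeric vector of length 18.
#' @export
regional_features <- function(duplex) {
  st <- duplex$status
  Mc <- length(st)
  reg <- list(seed = st[1:min(8L, Mc)],
              three = if (Mc > 8L) st[9:Mc] else integer(0),
              total = st)
  counts <- unlist(lapply(reg, function(s) vapply(1:4, function(k)
    sum(s == k), 0L)))
  b <- duplex$bulges
  out <- as.numeric(c(counts, b$seed["count"], b$seed["nt"],
                      b$three["count"], b$three["nt"], b$total["count"],
                      b$total["nt"]))
  names(out) <- c(paste0("n_", rep(c("wc", "gu", "mismatch", "gap"), 3), "_",
                         rep(c("seed", "three", "total"), each = 4)),
                  paste0("bulge_", rep(c("count", "nt"), 3), "_",
                         rep(c("seed", "three", "total"), each = 2)))
  out
}

# conservation scores over a 0-based coordinate run; off-UTR positions count
# as 0 with the nominal denominator
.region_cons_mean <- function(utr, coords) {
  ok <- coords >= 0 & coords < utr$length
  sum(utr$cons[coords[ok] + 1L]) / length(coords)
}

#' Conservation features (3 values)
#'
#' Mean per-nucleotide conservation over the seed binding region, the 5'
#' context r1..r10 and the 3' context q0..q-9. Absent scores count as 0.
#'
#' @param site a `CandidateSite`.
#' @param utr the parent `UtrSeq`.
#' @return named numeric vector of length 3.
#' @export
conservation_features <- function(site, utr) {
  out <- c(.region_cons_mean(utr, site$start:(site$end - 1L)),
           .region_cons_mean(utr, site$start - (1:10)),
           .region_cons_mean(utr, site$end + (0:9)))
  names(out) <- c("cons_seed", "cons_context5", "cons_context3")
  out
}

#' Energy features (4 values)
#'
#' Seed, 3' and total duplex binding energies plus the accessibility ddG,
#' passed through from the duplexer.
#'
#' @param duplex a `DuplexStructure`.
#' @param access an `AccessibilityResult`.
#' @return named numeric vector of length 4.
#' @export
energy_features <- function(duplex, access) {
  out <- c(duplex$e_seed, duplex$e_three, duplex$e_total, access$ddg)
  names(out) <- c("e_seed", "e_three", "e_total", "ddg")
  out
}

#' Seed context features (40 values)
#'
#' Composition block (20): A/C/G/U counts plus all 16 dinucleotide counts
#' pooled over the two 10-nt context regions (r1..r10 and q0..q-9);
#' positional block (20): nucleotide type code (1..4, 0 if off the UTR) at
#' each context position.
#'
#' @param site a `CandidateSite`.
#' @param utr the parent `UtrSeq`.
#' @return named numeric vector of length 40.
#' @export
context_features <- function(site, utr) {
  L <- utr$length
  code_at <- function(coords) {
    out <- rep(0L, length(coords))
    ok <- coords >= 0 & coords < L
    out[ok] <- utr$codes[coords[ok] + 1L]
    out
  }
  # positional order r1..r10 walks 5'-ward, q0..q-9 walks 3'-ward
  r_codes <- code_at(site$start - (1:10))
  q_codes <- code_at(site$end + (0:9))
  mono <- vapply(1:4, function(k) sum(r_codes == k) + sum(q_codes == k), 0L)
  # dinucleotides along the UTR 5'->3' direction within each region
  dimer_counts <- integer(16)
  for (reg in list(rev(r_codes), q_codes)) {
    for (i in seq_len(length(reg) - 1L)) {
      a <- reg[i]; b <- reg[i + 1L]
      if (a > 0L && b > 0L) {
        k <- 4L * (a - 1L) + b
        dimer_counts[k] <- dimer_counts[k] + 1L
      }
    }
  }
  dimers <- as.vector(t(outer(.NT_CHARS, .NT_CHARS, paste0)))
  out <- as.numeric(c(mono, dimer_counts, r_codes, q_codes))
  names(out) <- c(paste0("comp_", c(.NT_CHARS, dimers)),
                  paste0("pos_r", 1:10), paste0("pos_q", 0:-9))
  out
}

#' Site location features (3 values)
#'
#' Distance from the site to the stop codon (= UTR 5' end), distance to the
#' nearest UTR end, and that distance as a fraction of UTR length.
#'
#' @param site a `CandidateSite`.
#' @param utr the parent `UtrSeq`.
#' @return named numeric vector of length 3.
#' @export
location_features <- function(site, utr) {
  d5 <- site$start
  dmin <- min(site$start, utr$length - site$end)
  out <- c(d5, dmin, dmin / utr$length)
  names(out) <- c("dist_stop", "dist_nearest_end", "dist_ratio")
  out
}

#' Extract the full 113-feature site vector
#'
#' Concatenates the 7 groups in fixed order; computes the duplex structure
#' and accessibility internally unless supplied.
#'
#' @param site a `CandidateSite`.
#' @param utr the parent `UtrSeq`.
#' @param mirna the probing `MirnaSeq`.
#' @param duplex optional precomputed [fold_duplex()] result.
#' @param access optional precomputed [accessibility()] result.
#' @param params energy parameters.
#' @param window_pad accessibility folding pad.
#' @return named numeric vector of length 113.
#' @export
extract_site_features <- function(site, utr, mirna, duplex = NULL,
                                  access = NULL,
                                  params = default_energy_params(),
                                  window_pad = 70) {
  if (is.null(duplex)) duplex <- fold_duplex(mirna, site, utr, params)
  if (is.null(access))
    access <- accessibility(utr, site, dg_duplex = duplex$e_total,
                            window_pad = window_pad, params = params)
  out <- c(seed_match_features(site),
           pairwise_features(duplex),
           regional_features(duplex),
           conservation_features(site, utr),
           energy_features(duplex, access),
           context_features(site, utr),
           location_features(site, utr))
  stopifnot(length(out) == 113L)
  names(out) <- site_feature_names()
  out
}

# seed-category membership matrix for a list of sites: 7 columns
.site_categories <- function(sites) {
  if (!length(sites))
    return(matrix(FALSE, 0, 7, dimnames = list(NULL, .UTR_CATEGORIES)))
  flags <- t(vapply(sites, function(s) seed_match_features(s) > 0,
                    logical(6)))
  out <- cbind(flags, rowSums(flags) == 0)
  colnames(out) <- .UTR_CATEGORIES
  out
}

#' Extract the full 30-feature UTR vector
#'
#' Positive sites are candidate sites with decision score > 0. Category top
#' scores for empty categories take the [score_floor()] sentinel.
#'
#' @param utr a `UtrSeq`.
#' @param candidate_sites list of `CandidateSite` for one miRNA on this UTR.
#' @param site_scores numeric site-SVM decision scores, one per candidate.
#' @return named numeric vector of length 30.
#' @export
extract_utr_features <- function(utr, candidate_sites, site_scores) {
  stopifnot(length(candidate_sites) == length(site_scores))
  L <- utr$length
  n_pot <- length(candidate_sites)
  pos <- site_scores > 0
  starts <- vapply(candidate_sites, function(s) s$start, 0L)

  max_in_window <- function(sel) {
    ss <- sort(starts[sel])
    if (!length(ss)) return(0L)
    # the maximum over all 100-nt windows is attained at a window whose left
    # edge is a site start
    max(vapply(ss, function(w) sum(ss >= w & ss < w + 100L), 0L))
  }

  cats <- .site_categories(candidate_sites)
  cat_feats <- numeric(0)
  for (cn in .UTR_CATEGORIES) {
    inc <- if (n_pot) cats[, cn] else logical(0)
    topc <- if (any(inc)) max(site_scores[inc]) else score_floor()
    cat_feats <- c(cat_feats, sum(inc), sum(inc & pos), topc)
  }

  out <- c(L,
           n_pot / L, sum(pos) / L,
           max_in_window(rep(TRUE, n_pot)), max_in_window(pos),
           cat_feats,
           if (n_pot) max(site_scores) else score_floor(),
           sum(site_scores[pos]),
           sum(pos), n_pot)
  stopifnot(length(out) == 30L)
  names(out) <- utr_feature_names()
  out
}
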