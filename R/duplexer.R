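# miRNA:site duplex structure and energies.
#
# The energy model is a deliberately simplified nearest-neighbour scheme:
# only stacked pairs carry (negative) energy, read from a Turner-like table
# keyed by the miRNA-strand dinucleotide for pure Watson-Crick stacks and
# from two flat constants for stacks involving one or two G:U pairs; bulges
# pay an affine penalty, interior-loop nucleotides a flat per-nt penalty,
# dangling ends are free.  The parameters are configuration (the published
# tool's exact tables are unavailable); the dynamic programme, not the
# parameter values, is what the oracle tests pin down.

#' Default duplex/fold energy parameters
#'
#' @return list with components `stack_wc` (4x4 matrix of stack free energies
#'   in kcal/mol indexed by the miRNA-strand dinucleotide), `stack_gu1`,
#'   `stack_gu2` (stacks containing one/two G:U pairs), `bulge_open`,
#'   `bulge_ext`, `mismatch` (interior-loop penalty per nt).
#' @export
default_energy_params <- function() {
  E <- matrix(0, 4, 4, dimnames = list(.NT_CHARS, .NT_CHARS))
  E["A", "A"] <- -0.93; E["U", "U"] <- -0.93
  E["A", "U"] <- -1.10
  E["U", "A"] <- -1.33
  E["C", "U"] <- -2.08; E["A", "G"] <- -2.08
  E["C", "A"] <- -2.11; E["U", "G"] <- -2.11
  E["G", "U"] <- -2.24; E["A", "C"] <- -2.24
  E["G", "A"] <- -2.35; E["U", "C"] <- -2.35
  E["C", "G"] <- -2.36
  E["G", "G"] <- -3.26; E["C", "C"] <- -3.26
  E["G", "C"] <- -3.42
  list(stack_wc = E, stack_gu1 = -1.3, stack_gu2 = -0.5,
       bulge_open = 3.0, bulge_ext = 0.5, mismatch = 0.3)
}

#' Read energy parameters from a TSV
#'
#' Two columns `param`, `value`; stack entries are named `stack_XY` with X,Y
#' the miRNA-strand dinucleotide, scalars by their parameter name. Unlisted
#' parameters keep their defaults.
#'
#' @param path TSV file.
#' @return parameter list as [default_energy_params()].
#' @export
read_energy_params <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("param", "value") %in% names(df)))
    stop("energy parameter file needs columns 'param' and 'value'")
  p <- default_energy_params()
  for (i in seq_len(nrow(df))) {
    key <- df$param[i]; val <- as.numeric(df$value[i])
    if (grepl("^stack_[ACGU]{2}$", key)) {
      nts <- strsplit(sub("stack_", "", key), "")[[1]]
      p$stack_wc[nts[1], nts[2]] <- val
    } else if (key %in% names(p)) {
      p[[key]] <- val
    } else stop("unknown energy parameter: ", key)
  }
  p
}

# pair types: 1 A:U, 2 C:G, 3 G:C, 4 U:A, 5 G:U, 6 U:G (first = miRNA/top)
pair_type_code <- function(a, b) {
  key <- paste0(a, ",", b)
  unname(c("1,4" = 1L, "2,3" = 2L, "3,2" = 3L, "4,1" = 4L,
           "3,4" = 5L, "4,3" = 6L)[key])
}
.PT_TOP <- c(1L, 2L, 3L, 4L, 3L, 4L)  # miRNA-strand nt code of each pair type

# stack energy between consecutive pairs of types t1 (5') and t2 (3')
stack_energy <- function(params, t1, t2) {
  if (is.na(t1) || is.na(t2) || t1 == 0 || t2 == 0) return(0)
  n_gu <- (t1 >= 5) + (t2 >= 5)
  if (n_gu == 0) params$stack_wc[.PT_TOP[t1], .PT_TOP[t2]]
  else if (n_gu == 1) params$stack_gu1
  else params$stack_gu2
}

# 6x6 pair-type stack table for the intramolecular folder
stack_table6 <- function(params) {
  m <- matrix(0, 6, 6)
  for (t1 in 1:6) for (t2 in 1:6) m[t1, t2] <- stack_energy(params, t1, t2)
  m
}

# Score an explicit alignment column sequence.
# cols: data.frame with `status` (1-4) and `ptype` (pair type, 0 if unpaired).
# Stacks accrue between directly adjacent pair columns; interior runs of
# non-pair columns between two pairs pay mismatch/bulge penalties; leading
# and trailing non-pair columns (dangling ends) are free.
score_columns <- function(cols, params) {
  if (!nrow(cols)) return(0)
  is_pair <- cols$status <= 2L
  pk <- which(is_pair)
  if (!length(pk)) return(0)
  e <- 0
  for (w in seq_along(pk)[-1]) {
    a <- pk[w - 1]; b <- pk[w]
    if (b == a + 1) {
      e <- e + stack_energy(params, cols$ptype[a], cols$ptype[b])
    } else {
      run <- cols$status[(a + 1):(b - 1)]
      n_mm <- sum(run == 3L); n_gap <- sum(run == 4L)
      e <- e + params$mismatch * n_mm +
        if (n_gap > 0) params$bulge_open + params$bulge_ext * n_gap else 0
    }
  }
  e
}

# interior transition cost between pair columns separated by dm unpaired
# miRNA nts and dj unpaired site nts
.trans_cost <- function(dm, dj, t_prev, t_next, params) {
  if (dm == 0 && dj == 0)
    return(if (t_prev > 0) stack_energy(params, t_prev, t_next) else 0)
  k <- min(dm, dj); ex <- max(dm, dj) - k
  params$mismatch * k +
    if (ex > 0) params$bulge_open + params$bulge_ext * ex else 0
}

#' Fold the miRNA:site hybrid duplex
#'
#' The seed alignment found by the filter is kept as a hard constraint; the
#' 3' region (miRNA p9..p20 against the UTR nucleotides 5' of the site) is
#' aligned by dynamic programming over increasing pair sequences under the
#' configured energy model, with free dangling ends. Only the first 20 miRNA
#' nucleotides are considered.
#'
#' @param mirna a `MirnaSeq`.
#' @param site a `CandidateSite` from [scan_sites()].
#' @param utr the parent `UtrSeq`.
#' @param params energy parameters, see [default_energy_params()].
#' @param max_bulge maximum bulged site nucleotides allowed in the 3' region.
#' @return object of class `DuplexStructure`: `status` (per miRNA position
#'   1..min(M,20)), `dimer_code` (miRNA 2-mer codes 1..16), `seed_boundary`
#'   (site nucleotides consumed by the seed, i.e. the q index pairing p8),
#'   `e_seed`, `e_three`, `e_total` (kcal/mol), and `bulges` (site-side
#'   bulge count and bulged nt count per region).
#' @export
fold_duplex <- function(mirna, site, utr, params = default_energy_params(),
                        max_bulge = 4L) {
  stopifnot(inherits(mirna, "MirnaSeq"), inherits(site, "CandidateSite"),
            inherits(utr, "UtrSeq"))
  if (site$end - site$start < 6)
    stop("degenerate input: site shorter than 6 nt")
  Mc <- min(mirna$M, 20L)
  u <- utr$codes
  mcod <- mirna$codes

  # --- seed columns (fixed by the filter) ---------------------------------
  st <- site$statuses
  mi <- site$mirna_index
  coord <- site$end - 1L              # UTR coordinate (0-based) of q1
  seed_status <- integer(length(st))
  seed_ptype <- integer(length(st))
  seed_bulge_nt <- 0L; seed_bulge_ct <- 0L
  for (k in seq_along(st)) {
    if (st[k] == 4L && !is.na(mi[k])) {        # miRNA bulged: no UTR nt used
      seed_status[k] <- 4L; seed_ptype[k] <- 0L
      next
    }
    if (st[k] == 4L) {                          # UTR-side bulge column
      seed_status[k] <- 4L; seed_ptype[k] <- 0L
      seed_bulge_ct <- seed_bulge_ct + 1L
      seed_bulge_nt <- seed_bulge_nt + 1L
    } else {
      a <- mcod[mi[k]]; b <- if (coord >= 0) u[coord + 1L] else NA_integer_
      seed_status[k] <- st[k]
      pt <- if (st[k] <= 2L && !is.na(b)) pair_type_code(a, b) else 0L
      seed_ptype[k] <- if (is.na(pt) || is.null(pt)) 0L else pt
    }
    coord <- coord - 1L
  }
  seed_cols <- data.frame(status = seed_status, ptype = seed_ptype)
  e_seed <- score_columns(seed_cols, params)
  n_seed <- site$end - site$start     # q index of the nt pairing p8

  # per-miRNA-position seed statuses (drop UTR-bulge columns)
  status <- rep(3L, Mc)
  keep <- !is.na(mi)
  status[mi[keep]] <- seed_status[keep]

  # --- 3' region DP --------------------------------------------------------
  e_three <- 0; junction <- 0
  three_bulge_ct <- 0L; three_bulge_nt <- 0L
  if (Mc >= 9L && site$start > 0L) {
    # junction stacking is only possible when p8 itself is paired
    last_col <- nrow(seed_cols)
    t0 <- if (seed_cols$status[last_col] <= 2L) seed_ptype[last_col] else 0L
    n_m <- Mc - 8L
    Kr <- min(site$start, n_m + max_bulge)      # r indices 1..Kr
    rc <- site$start - seq_len(Kr)              # 0-based coords of r1..rKr
    ptype <- matrix(0L, n_m, Kr)
    for (a in seq_len(n_m)) {
      for (j in seq_len(Kr)) {
        pt <- pair_type_code(mcod[8L + a], u[rc[j] + 1L])
        ptype[a, j] <- if (is.na(pt) || is.null(pt)) 0L else pt
      }
    }
    dp <- matrix(Inf, n_m, Kr)
    prev <- matrix(0L, n_m, Kr)                 # encoded predecessor
    for (a in seq_len(n_m)) {
      for (j in seq_len(Kr)) {
        if (ptype[a, j] == 0L) next
        # from the seed junction: leading unpaired nts are free
        best <- if (a == 1L && j == 1L && t0 > 0L)
          stack_energy(params, t0, ptype[a, j]) else 0
        bp <- 0L
        if (a > 1L) {
          for (a0 in seq_len(a - 1L)) for (j0 in seq_len(min(j - 1L, Kr))) {
            if (!is.finite(dp[a0, j0])) next
            v <- dp[a0, j0] +
              .trans_cost(a - a0 - 1L, j - j0 - 1L, ptype[a0, j0],
                          ptype[a, j], params)
            if (v < best) { best <- v; bp <- a0 * 1000L + j0 }
          }
        }
        dp[a, j] <- best
        prev[a, j] <- bp
      }
    }
    finite <- which(is.finite(dp))
    if (length(finite) && min(dp[finite]) < 0) {
      endk <- finite[which.min(dp[finite])]
      e3j <- dp[endk]
      # traceback
      path <- integer(0)
      cur <- endk
      repeat {
        path <- c(cur, path)
        a <- (cur - 1L) %% n_m + 1L; j <- (cur - 1L) %/% n_m + 1L
        bp <- prev[a, j]
        if (bp == 0L) break
        cur <- (bp %/% 1000L - 1L) + n_m * ((bp %% 1000L) - 1L) + 1L
      }
      pa <- (path - 1L) %% n_m + 1L
      pj <- (path - 1L) %/% n_m + 1L
      first_adj <- pa[1] == 1L && pj[1] == 1L && t0 > 0L
      junction <- if (first_adj)
        stack_energy(params, t0, ptype[pa[1], pj[1]]) else 0
      e_three <- e3j - junction
      # statuses for 3' miRNA positions: WC/GU from the pair type
      for (w in seq_along(pa))
        status[8L + pa[w]] <- if (ptype[pa[w], pj[w]] <= 4L) 1L else 2L
      # interior runs between consecutive pairs: unpaired miRNA nts up to
      # the site-side count are mismatches, the excess is gapped (bulged
      # miRNA); site-side excess counts as a bulged structure on the mRNA
      if (length(pa) > 1L) {
        for (w in 2:length(pa)) {
          dm <- pa[w] - pa[w - 1L] - 1L
          dj <- pj[w] - pj[w - 1L] - 1L
          if (dm > dj && dm > 0L) {
            lo <- 8L + pa[w - 1L] + 1L
            status[(lo + dj):(lo + dm - 1L)] <- 4L
          }
          if (dj > dm) {
            three_bulge_ct <- three_bulge_ct + 1L
            three_bulge_nt <- three_bulge_nt + (dj - dm)
          }
        }
      }
    }
  }

  e_total <- e_seed + e_three + junction

  dimer <- 4L * (mcod[seq_len(Mc - 1L)] - 1L) + mcod[2:Mc]

  structure(list(
    mirna_id = mirna$id, utr_id = utr$id,
    site_start = site$start, site_end = site$end,
    status = status,
    dimer_code = as.integer(dimer),
    seed_boundary = as.integer(n_seed),
    e_seed = e_seed, e_three = e_three, e_total = e_total,
    junction = junction,
    bulges = list(seed = c(count = seed_bulge_ct, nt = seed_bulge_nt),
                  three = c(count = three_bulge_ct, nt = three_bulge_nt),
                  total = c(count = seed_bulge_ct + three_bulge_ct,
                            nt = seed_bulge_nt + three_bulge_nt))),
    class = "DuplexStructure")
}

#' @export
print.DuplexStructure <- function(x, ...) {
  cat("<DuplexStructure> ", x$mirna_id, " x ", x$utr_id, " [", x$site_start,
      ",", x$site_end, ")\n  status: ", paste(x$status, collapse = ""),
      "\n  e_seed=", round(x$e_seed, 2), " e_three=", round(x$e_three, 2),
      " e_total=", round(x$e_total, 2), " kcal/mol\n", sep = "")
  invisible(x)
}

#' Stack-only intramolecular MFE of an RNA segment
#'
#' R wrapper around the C++ folder used by the accessibility backend: nested
#' structures, minimum hairpin loop 3, only stacked pairs score.
#'
#' @param codes integer nucleotide codes (or an RNA string).
#' @param can_pair logical per-position pairing permission.
#' @param params energy parameters.
#' @return minimum free energy (kcal/mol, <= 0).
#' @export
fold_mfe <- function(codes, can_pair = NULL, params = default_energy_params()) {
  if (is.character(codes)) codes <- encode_rna(codes)
  if (is.null(can_pair)) can_pair <- rep(TRUE, length(codes))
  fold_mfe_cpp(as.integer(codes), can_pair, stack_table6(params))
}

#' Site accessibility energy
#'
#' PITA-style openness: the cost of freeing the site from local UTR secondary
#' structure. The UTR window `site +/- window_pad` is folded twice by the
#' builtin backend (stack-only MFE), once unconstrained and once with the
#' site positions forbidden to pair; the opening cost is the difference and
#' ddg = duplex energy + opening cost (less negative = less favourable).
#'
#' @param utr a `UtrSeq`.
#' @param site a `CandidateSite`.
#' @param dg_duplex duplex free energy (e_total of [fold_duplex()]).
#' @param window_pad nucleotides of flanking context folded with the site.
#' @param params energy parameters.
#' @param backend "builtin" (DP folder) or "heuristic" (pairing-propensity
#'   fallback, flagged in the result).
#' @return object of class `AccessibilityResult`: `ddg`, `dg_open` (>= 0
#'   opening cost), `window` (0-based half-open interval folded), `backend`.
#' @export
accessibility <- function(utr, site, dg_duplex = 0, window_pad = 70,
                          params = default_energy_params(),
                          backend = c("builtin", "heuristic")) {
  backend <- match.arg(backend)
  stopifnot(inherits(utr, "UtrSeq"), inherits(site, "CandidateSite"))
  w0 <- max(0L, site$start - as.integer(window_pad))
  w1 <- min(utr$length, site$end + as.integer(window_pad))
  codes <- utr$codes[(w0 + 1L):w1]
  in_site <- seq(w0, w1 - 1L) >= site$start & seq(w0, w1 - 1L) < site$end
  if (backend == "builtin") {
    free <- fold_mfe(codes, rep(TRUE, length(codes)), params)
    constr <- fold_mfe(codes, !in_site, params)
    dg_open <- constr - free                    # >= 0
  } else {
    # crude pairing-propensity proxy: how much of the flanking sequence can
    # complement the site at all, scaled to a plausible kcal range
    flank <- codes[!in_site]; sc <- codes[in_site]
    comp <- vapply(sc, function(a)
      mean(pair_status_code(rep(a, length(flank)), flank) <= 2L), 0)
    dg_open <- 4 * mean(comp) * length(sc) / 8
  }
  structure(list(ddg = dg_duplex + dg_open, dg_open = dg_open,
                 window = c(start = w0, end = w1), backend = backend,
                 fallback = backend != "builtin"),
            class = "AccessibilityResult")
}
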