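# Domain types and I/O for sequences, conservation tracks and tabular records.
#
# Coordinate conventions used throughout the package:
#  * UTR coordinates are 0-based half-open on the 5'->3' strand.
#  * miRNA positions p1..pM are 1-based from the miRNA 5' end.
#  * Site positions q1..qN are numbered from the site 3' end so that q1 is the
#    UTR nucleotide opposite p1; pairing is antiparallel, so increasing q index
#    walks 3'->5' (decreasing coordinate) along the UTR.  q0, q-1, ... denote
#    the 3' context (downstream of the site), r1, r2, ... the 5' context.

.NT_CHARS <- c("A", "C", "G", "U")
.NT_CODES <- c(A = 1L, C = 2L, G = 3L, U = 4L)

# pair status codes: 1 = Watson-Crick, 2 = G:U wobble, 3 = mismatch, 4 = gap
.STATUS <- local({
  m <- matrix(3L, 4, 4, dimnames = list(.NT_CHARS, .NT_CHARS))
  m["A", "U"] <- m["U", "A"] <- 1L
  m["C", "G"] <- m["G", "C"] <- 1L
  m["G", "U"] <- m["U", "G"] <- 2L
  m
})

normalize_rna <- function(s) {
  s <- chartr("tu", "TU", toupper(s))
  gsub("T", "U", s, fixed = TRUE)
}

#' Encode an RNA string as integer codes
#'
#' A=1, C=2, G=3, U=4. Input is upper-cased and T is converted to U.
#'
#' @param s character scalar over the RNA/DNA alphabet.
#' @return integer vector of codes.
#' @export
encode_rna <- function(s) {
  s <- normalize_rna(s)
  v <- .NT_CODES[strsplit(s, "", fixed = TRUE)[[1]]]
  if (anyNA(v)) {
    bad <- unique(setdiff(strsplit(s, "")[[1]], .NT_CHARS))
    stop("illegal character(s) in sequence: ", paste(bad, collapse = ", "))
  }
  unname(v)
}

decode_rna <- function(codes) paste(.NT_CHARS[codes], collapse = "")

# status of the pair (miRNA code a, UTR code b); 0 codes mean "absent"
pair_status_code <- function(a, b) {
  out <- rep(3L, length(a))
  ok <- a >= 1L & a <= 4L & b >= 1L & b <= 4L
  out[ok] <- .STATUS[cbind(a[ok], b[ok])]
  out
}

#' Construct a miRNA sequence record
#'
#' @param id record identifier.
#' @param seq RNA sequence 5'->3' (T accepted and converted to U).
#' @return object of class `MirnaSeq` with fields `id`, `seq`, `codes`, `M`.
#' @export
mirna_seq <- function(id, seq) {
  if (!nzchar(seq)) stop("empty sequence for miRNA record '", id, "'")
  codes <- encode_rna(seq)
  structure(list(id = as.character(id), seq = decode_rna(codes),
                 codes = codes, M = length(codes)),
            class = "MirnaSeq")
}

#' Construct a 3'UTR sequence record
#'
#' @param id record identifier.
#' @param seq RNA sequence 5'->3'.
#' @param gene gene symbol (defaults to the id).
#' @param cons optional per-nucleotide conservation scores in \[0, 1\], same
#'   length as `seq`.
#' @return object of class `UtrSeq` with fields `id`, `gene`, `seq`, `codes`,
#'   `length`, `cons`, `has_cons`.
#' @export
utr_seq <- function(id, seq, gene = id, cons = NULL) {
  if (!nzchar(seq)) stop("empty sequence for UTR record '", id, "'")
  codes <- encode_rna(seq)
  has_cons <- !is.null(cons)
  if (has_cons) {
    if (length(cons) != length(codes))
      stop("conservation length differs from sequence length for '", id, "'")
    if (any(cons < 0 | cons > 1, na.rm = TRUE))
      stop("conservation scores outside [0,1] for '", id, "'")
    cons[is.na(cons)] <- 0
  } else {
    cons <- rep(0, length(codes))
  }
  structure(list(id = as.character(id), gene = as.character(gene),
                 seq = decode_rna(codes), codes = codes,
                 length = length(codes), cons = cons, has_cons = has_cons),
            class = "UtrSeq")
}

#' @export
print.MirnaSeq <- function(x, ...) {
  cat("<MirnaSeq>", x$id, " M=", x$M, " ", x$seq, "\n", sep = "")
  invisible(x)
}

#' @export
print.UtrSeq <- function(x, ...) {
  cat("<UtrSeq>", x$id, " (", x$gene, ") length=", x$length,
      if (x$has_cons) " +cons" else "", "\n", sep = "")
  invisible(x)
}

#' Construct a candidate binding site
#'
#' `start`/`end` delimit the seed-paired UTR interval (0-based half-open);
#' q1 sits at coordinate `end - 1`.
#'
#' @param utr_id,mirna_id parent record identifiers.
#' @param start,end 0-based half-open interval on the UTR.
#' @param rule_id which of the 5 seed-match filter rules fired (lowest id).
#' @param statuses seed alignment column statuses (1 WC, 2 GU, 3 mismatch,
#'   4 gap), 5'->3' in miRNA order.
#' @param mirna_index miRNA position of each alignment column (NA for a
#'   UTR-side bulge column).
#' @param n_wc,n_match Watson-Crick and total match counts of the seed
#'   alignment.
#' @param gap_count number of gap columns (0 or 1).
#' @param seed_string UTR sequence of the site interval, 5'->3'.
#' @param utr_length length of the parent UTR, used for validation.
#' @return object of class `CandidateSite`.
#' @export
candidate_site <- function(utr_id, mirna_id, start, end, rule_id,
                           statuses, mirna_index, n_wc, n_match,
                           gap_count = 0L, seed_string = "",
                           utr_length = NULL) {
  if (start < 0 || end <= start)
    stop("invalid site interval [", start, ",", end, ")")
  if (!is.null(utr_length) && end > utr_length)
    stop("site interval exceeds UTR length")
  if (!rule_id %in% 1:5) stop("rule_id must be in 1..5")
  structure(list(utr_id = utr_id, mirna_id = mirna_id,
                 start = as.integer(start), end = as.integer(end),
                 rule_id = as.integer(rule_id),
                 statuses = as.integer(statuses),
                 mirna_index = mirna_index,
                 n_wc = as.integer(n_wc), n_match = as.integer(n_match),
                 gap_count = as.integer(gap_count),
                 seed_string = seed_string),
            class = "CandidateSite")
}

#' @export
print.CandidateSite <- function(x, ...) {
  cat("<CandidateSite> ", x$mirna_id, " x ", x$utr_id, " [", x$start, ",",
      x$end, ") rule ", x$rule_id, " WC=", x$n_wc, " match=", x$n_match,
      "\n", sep = "")
  invisible(x)
}

#' Map a site q index to a UTR coordinate
#'
#' q1 maps to `end - 1`; increasing q walks 3'->5' (towards `start`);
#' q0, q-1, ... walk into the 3' context. Returns NA for coordinates falling
#' off the UTR when `utr_length` is supplied.
#'
#' @param site a `CandidateSite`.
#' @param k q index (integer, may be <= 0 for 3' context).
#' @param utr_length optional UTR length used to bound-check.
#' @return 0-based UTR coordinate (or NA if out of bounds).
#' @export
q_to_coord <- function(site, k, utr_length = NULL) {
  coord <- site$end - k
  if (!is.null(utr_length)) coord[coord < 0 | coord >= utr_length] <- NA_integer_
  coord
}

#' Map a 5' context r index to a UTR coordinate
#'
#' r1 = q_{n+1} is the first nucleotide 5' of the seed-paired interval, i.e.
#' coordinate `start - 1`.
#'
#' @inheritParams q_to_coord
#' @export
r_to_coord <- function(site, k, utr_length = NULL) {
  coord <- site$start - k
  if (!is.null(utr_length)) coord[coord < 0 | coord >= utr_length] <- NA_integer_
  coord
}

#' Construct a labeled miRNA/UTR training pair
#'
#' @param mirna_id,utr_id record identifiers.
#' @param label "positive" or "negative".
#' @param level "site" or "utr".
#' @param site a `CandidateSite` (required iff `level == "site"`).
#' @return object of class `LabeledPair`.
#' @export
labeled_pair <- function(mirna_id, utr_id, label, level, site = NULL) {
  label <- match.arg(label, c("positive", "negative"))
  level <- match.arg(level, c("site", "utr"))
  if (level == "site" && is.null(site))
    stop("site-level pair requires a CandidateSite")
  if (level == "utr" && !is.null(site))
    stop("utr-level pair must not carry a site")
  structure(list(mirna_id = mirna_id, utr_id = utr_id, label = label,
                 level = level, site = site),
            class = "LabeledPair")
}

# ---------------------------------------------------------------------------
# FASTA

#' Read miRNA or UTR sequences from a FASTA file
#'
#' Records are returned in file order; sequences are upper-cased and T is
#' converted to U. Duplicate identifiers, empty sequences and illegal
#' characters raise an error naming the offending record.
#'
#' @param path FASTA file.
#' @param molecule "mirna" or "utr".
#' @return named list of `MirnaSeq` or `UtrSeq` records.
#' @export
read_fasta <- function(path, molecule = c("mirna", "utr")) {
  molecule <- match.arg(molecule)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    out[[i]] <- tryCatch(
      if (molecule == "mirna") mirna_seq(ids[i], seqs[i])
      else utr_seq(ids[i], seqs[i]),
      error = function(e) stop("record '", ids[i], "': ", conditionMessage(e),
                               call. = FALSE))
  }
  names(out) <- ids
  message(length(out), " ", molecule, " record(s) read from ", path)
  out
}

#' Write sequence records to a FASTA file
#'
#' @param records list of `MirnaSeq`/`UtrSeq` records.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) writeLines(c(paste0(">", r$id), r$seq), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Conservation tracks

#' Attach per-nucleotide conservation scores to UTR records
#'
#' Accepts fixedStep/variableStep wiggle or 4-column bedGraph; track
#' "chromosome" names must be UTR ids, coordinates are interpreted against
#' the UTR (wiggle is 1-based, bedGraph 0-based half-open, both handled by
#' the importer). Positions without coverage get score 0 and `has_cons`
#' records whether any real score was present.
#'
#' @param path track file.
#' @param utrs named list of `UtrSeq`.
#' @param format "auto", "wig" or "bedGraph".
#' @return the UTR list with `cons`/`has_cons` filled in.
#' @export
read_conservation <- function(path, utrs, format = c("auto", "wig", "bedGraph")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("bedgraph", "bg")) "bedGraph" else "wig"
  }
  gr <- rtracklayer::import(path, format = format)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)   # 1-based
  ends <- GenomicRanges::end(gr)
  score <- gr$score
  if (any(score < 0 | score > 1))
    stop("conservation score(s) outside [0,1] in ", path)
  n_attached <- 0L
  for (id in names(utrs)) {
    u <- utrs[[id]]
    sel <- which(chrom == id)
    cons <- rep(0, u$length)
    covered <- FALSE
    for (k in sel) {
      lo <- max(1L, starts[k])
      hi <- min(u$length, ends[k])
      if (lo <= hi) {
        cons[lo:hi] <- score[k]
        covered <- TRUE
      }
    }
    u$cons <- cons
    u$has_cons <- covered
    utrs[[id]] <- u
    if (covered) n_attached <- n_attached + 1L
  }
  message("conservation attached for ", n_attached, "/", length(utrs),
          " UTR(s) from ", path)
  utrs
}

#' Write conservation tracks as fixedStep wiggle
#'
#' @param utrs named list of `UtrSeq` with `cons` filled.
#' @param path output file.
#' @export
write_conservation <- function(utrs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (u in utrs) {
    writeLines(paste0("fixedStep chrom=", u$id, " start=1 step=1"), con)
    writeLines(format(u$cons, trim = TRUE, scientific = FALSE, digits = 6), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Tabular records

#' Read a differential-expression table
#'
#' @param path TSV with a header row.
#' @param col_map named character vector mapping the canonical column names
#'   `gene`, `log_fold_change`, `p_value` to the file's column names.
#' @return data.frame with the canonical columns first; any further columns
#'   (e.g. per-timepoint fold changes) are preserved.
#' @export
read_expression_table <- function(path,
                                  col_map = c(gene = "gene",
                                              log_fold_change = "log_fold_change",
                                              p_value = "p_value")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene", "log_fold_change", "p_value")
  missing_cols <- setdiff(need, names(col_map))
  if (length(missing_cols))
    stop("col_map lacks mapping for: ", paste(missing_cols, collapse = ", "))
  absent <- setdiff(unname(col_map[need]), names(df))
  if (length(absent))
    stop("mandatory column(s) missing from ", path, ": ",
         paste(absent, collapse = ", "))
  extra <- setdiff(names(df), unname(col_map[need]))
  out <- data.frame(gene = as.character(df[[col_map["gene"]]]),
                    log_fold_change = as.numeric(df[[col_map["log_fold_change"]]]),
                    p_value = as.numeric(df[[col_map["p_value"]]]),
                    stringsAsFactors = FALSE)
  for (cn in extra) out[[cn]] <- df[[cn]]
  message(nrow(out), " expression row(s) read from ", path)
  out
}

#' Read labeled miRNA/UTR pairs from a TSV
#'
#' Expected columns: mirna_id, utr_id, label, level and (for site-level rows)
#' start, end.
#'
#' @param path TSV file with header.
#' @return data.frame of pair records.
#' @export
read_labeled_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "utr_id", "label", "level")
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop("labeled-pair table lacks column(s): ", paste(absent, collapse = ", "))
  message(nrow(df), " labeled pair(s) read from ", path)
  df
}

#' Write labeled pairs to a TSV
#'
#' @param pairs data.frame as returned by [read_labeled_pairs()].
#' @param path output file.
#' @export
write_labeled_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
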