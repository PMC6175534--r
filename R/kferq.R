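# KFERQ-like motif scanner for endosomal microautophagy targeting sequences.
#
# A five-residue window is a KFERQ-like motif when it begins or ends with Q
# and, over the four residues excluding that anchor Q, contains one or two
# basic residues (K, R), one or two bulky hydrophobic residues (F, I, L, V)
# and exactly one acidic residue (D, E). With four available slots the class
# counts total 3 or 4; the default accepts the 1/1/1 case with one
# unconstrained residue, the strict variant requires all four slots to be
# class members. Interior glutamines count as unconstrained.

.KFERQ_BASIC <- c("K", "R")
.KFERQ_HYDRO <- c("F", "I", "L", "V")
.KFERQ_ACID <- c("D", "E")
.AA_INVALID <- c("B", "J", "O", "U", "X", "Z")

# vectorized rule evaluation over many 5-letter windows
.kferq_eval <- function(windows, strict = FALSE) {
  n <- length(windows)
  if (!n)
    return(data.frame(window = character(), valid = logical(),
                      anchor = character(), n_basic = integer(),
                      n_hydrophobic = integer(), n_acidic = integer(),
                      stringsAsFactors = FALSE))
  w <- toupper(windows)
  if (any(nchar(w) != 5L))
    stop("windows must be exactly 5 residues long")
  ch <- matrix("", n, 5L)
  for (i in 1:5) ch[, i] <- substr(w, i, i)
  bad <- !grepl(paste0("^[", paste(.AA_STANDARD, collapse = ""), "]{5}$"), w)
  isb <- matrix(ch %in% .KFERQ_BASIC, n, 5L)
  ish <- matrix(ch %in% .KFERQ_HYDRO, n, 5L)
  isa <- matrix(ch %in% .KFERQ_ACID, n, 5L)
  counts <- function(m, cols) as.integer(rowSums(m[, cols, drop = FALSE]))
  ok <- function(b, h, a)
    b >= 1L & b <= 2L & h >= 1L & h <= 2L & a == 1L &
      (!strict | (b + h + a) == 4L)
  b_end <- counts(isb, 1:4); h_end <- counts(ish, 1:4); a_end <- counts(isa, 1:4)
  b_sta <- counts(isb, 2:5); h_sta <- counts(ish, 2:5); a_sta <- counts(isa, 2:5)
  end_ok <- !bad & ch[, 5] == "Q" & ok(b_end, h_end, a_end)
  sta_ok <- !bad & ch[, 1] == "Q" & ok(b_sta, h_sta, a_sta)
  valid <- end_ok | sta_ok
  anchor <- rep(NA_character_, n)
  anchor[valid] <- ifelse(ch[valid, 1] == "Q" & ch[valid, 5] == "Q", "both",
                          ifelse(end_ok[valid], "end", "start"))
  use_end <- end_ok | (!sta_ok & ch[, 5] == "Q")
  data.frame(window = w, valid = valid, anchor = anchor,
             n_basic = ifelse(use_end, b_end, b_sta),
             n_hydrophobic = ifelse(use_end, h_end, h_sta),
             n_acidic = ifelse(use_end, a_end, a_sta),
             stringsAsFactors = FALSE)
}

#' Classify a five-residue window as a KFERQ-like motif
#'
#' @param window A 5-letter amino-acid string (case-insensitive).
#' @param strict If `TRUE`, require all four non-anchor residues to belong
#'   to a composition class (no unconstrained residue); the default also
#'   accepts the 1 basic / 1 hydrophobic / 1 acidic case with one free slot.
#' @return A list with `valid`, `anchor` (`"start"`, `"end"`, `"both"`, or
#'   `NA`), and the composition counts `n_basic`, `n_hydrophobic`,
#'   `n_acidic` over the four non-anchor residues.
#' @examples
#' kferq_classify_window("KFERQ")$valid   # TRUE, the canonical motif
#' kferq_classify_window("QAAAA")$valid   # FALSE
#' @export
kferq_classify_window <- function(window, strict = FALSE) {
  if (length(window) != 1L) stop("'window' must be a single string")
  r <- .kferq_eval(window, strict)
  list(valid = r$valid, anchor = r$anchor, n_basic = r$n_basic,
       n_hydrophobic = r$n_hydrophobic, n_acidic = r$n_acidic)
}

#' Scan a protein sequence for KFERQ-like motifs
#'
#' Every overlapping five-residue window is evaluated; all valid windows are
#' reported in ascending start order with 0-based, half-open coordinates.
#'
#' @param sequence Amino-acid string (case-insensitive).
#' @param protein_id Identifier carried into the hit table.
#' @param strict Passed to the window classifier.
#' @return Data.frame of hits: `protein_id`, `start` (0-based), `window`,
#'   `anchor`, `n_basic`, `n_hydrophobic`, `n_acidic`. Sequences shorter
#'   than 5 residues yield zero hits with a warning.
#' @examples
#' kferq_scan("AAKFERQAA")$start  # 2
#' @export
kferq_scan <- function(sequence, protein_id = "seq", strict = FALSE) {
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  empty <- data.frame(protein_id = character(), start = integer(),
                      window = character(), anchor = character(),
                      n_basic = integer(), n_hydrophobic = integer(),
                      n_acidic = integer(), stringsAsFactors = FALSE)
  if (L < 5L) {
    warning("sequence for ", protein_id, " shorter than 5 residues; no windows")
    return(empty)
  }
  starts <- seq_len(L - 4L)
  wins <- substring(s, starts, starts + 4L)
  r <- .kferq_eval(wins, strict)
  hit <- which(r$valid)
  if (!length(hit)) return(empty)
  data.frame(protein_id = protein_id, start = starts[hit] - 1L,
             window = r$window[hit], anchor = r$anchor[hit],
             n_basic = r$n_basic[hit], n_hydrophobic = r$n_hydrophobic[hit],
             n_acidic = r$n_acidic[hit], stringsAsFactors = FALSE)
}

#' Annotate a proteome with KFERQ-like motif calls
#'
#' Accepts a FASTA file path, a [Biostrings::AAStringSet], or a named
#' character vector of sequences; scans every protein and tabulates motif
#' presence.
#'
#' @param fasta FASTA path, `AAStringSet`, or named character vector.
#' @param strict Passed to the window classifier.
#' @return Data.frame `protein_id`, `has_motif`, `n_hits`,
#'   `first_hit_start` (0-based, `NA` when motif-free), with the full hit
#'   table in the `"hits"` attribute. Duplicate ids are an error.
#' @export
annotate_proteome <- function(fasta, strict = FALSE) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    lines <- readLines(fasta, n = 1000L)
    first <- which(nzchar(trimws(lines)))[1]
    if (!is.na(first) && !startsWith(trimws(lines[first]), ">"))
      stop("malformed FASTA ", fasta, ": line ", first,
           " is not a header line")
    aa <- Biostrings::readAAStringSet(fasta)
    seqs <- stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  } else if (methods::is(fasta, "AAStringSet")) {
    seqs <- stats::setNames(as.character(fasta), sub("\\s.*$", "", names(fasta)))
  } else if (is.character(fasta)) {
    seqs <- fasta
  } else stop("unsupported input type for 'fasta'")
  if (length(seqs) && (is.null(names(seqs)) || any(!nzchar(names(seqs)))))
    stop("all sequences must be named")
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    stop("duplicate protein id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  if (!length(seqs)) {
    out <- data.frame(protein_id = character(), has_motif = logical(),
                      n_hits = integer(), first_hit_start = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "hits") <- kferq_scan("AAAAA")[0, ]
    return(out)
  }
  hits <- do.call(rbind, lapply(names(seqs), function(id)
    kferq_scan(seqs[[id]], id, strict)))
  n_hits <- table(factor(hits$protein_id, levels = names(seqs)))
  firsts <- vapply(names(seqs), function(id) {
    st <- hits$start[hits$protein_id == id]
    if (length(st)) min(st) else NA_integer_
  }, 1L)
  out <- data.frame(protein_id = names(seqs),
                    has_motif = as.integer(n_hits) > 0L,
                    n_hits = as.integer(n_hits),
                    first_hit_start = unname(firsts),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "hits") <- hits
  out
}
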