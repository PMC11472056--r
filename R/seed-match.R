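# Seed region definition and 3'UTR seed-complement scanning.
#
# The seed region of an siRNA guide strand is nucleotides 2-8 from the 5'
# end; a transcript whose 3'UTR contains the reverse complement of the seed
# is a potential miRNA-like off-target ("seed-matched", SM).

RNA_BASES <- c("A", "C", "G", "U")

normalize_rna <- function(seq) {
  s <- toupper(as.character(seq))
  chartr("T", "U", s)
}

#' Construct an siRNA guide strand
#'
#' Normalizes the sequence to uppercase RNA (T is accepted and converted to
#' U) and validates the alphabet. Modification tags (e.g. `"FA"` for a
#' 2'-formamido sugar) can be attached to 1-based positions.
#'
#' @param seq 5' to 3' sequence over A/C/G/U (T accepted), length 8-30
#' @param name optional strand name
#' @param mod_positions optional named character vector or list mapping
#'   1-based positions to modification tags
#' @return object of class `guide_strand`
#' @examples
#' guide_strand("ACUGCUACGAU", name = "entry1")
#' @export
guide_strand <- function(seq, name = "", mod_positions = NULL) {
  s <- normalize_rna(seq)
  if (length(s) != 1L) stop("seq must be a single string")
  n <- nchar(s)
  if (n < 8L || n > 30L) {
    stop("guide strand length must be between 8 and 30 nt, got ", n)
  }
  bad <- setdiff(strsplit(s, "")[[1L]], RNA_BASES)
  if (length(bad)) {
    stop("invalid guide characters: ", paste(unique(bad), collapse = ", "))
  }
  mods <- NULL
  if (!is.null(mod_positions)) {
    pos <- as.integer(names(mod_positions))
    if (anyNA(pos) || any(pos < 1L) || any(pos > n)) {
      stop("mod_positions names must be 1-based positions within the strand")
    }
    mods <- stats::setNames(as.character(unlist(mod_positions)), pos)
  }
  structure(
    list(name = as.character(name), seq = s, mod_positions = mods),
    class = "guide_strand"
  )
}

#' @export
print.guide_strand <- function(x, ...) {
  cat(sprintf("siRNA guide strand%s: 5'-%s-3' (%d nt)\n",
              if (nzchar(x$name)) paste0(" ", x$name) else "",
              x$seq, nchar(x$seq)))
  if (!is.null(x$mod_positions)) {
    cat("  modifications:",
        paste(sprintf("%s@%s", x$mod_positions, names(x$mod_positions)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

as_guide_seq <- function(guide) {
  if (inherits(guide, "guide_strand")) guide$seq else guide_strand(guide)$seq
}

#' Reverse complement of an RNA or DNA sequence
#'
#' Watson-Crick reverse complement; RNA mode pairs U with A, DNA mode T
#' with A. Any other character is an error.
#'
#' @param seq a single sequence string
#' @param alphabet `"RNA"` (default) or `"DNA"`
#' @return the reverse complement, 5' to 3'
#' @examples
#' reverse_complement("CUGCUAC")
#' @export
reverse_complement <- function(seq, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  s <- toupper(as.character(seq))
  if (length(s) != 1L) stop("seq must be a single string")
  valid <- if (alphabet == "RNA") "ACGU" else "ACGT"
  bad <- setdiff(strsplit(s, "")[[1L]], strsplit(valid, "")[[1L]])
  if (length(bad)) {
    stop("invalid ", alphabet, " characters: ",
         paste(unique(bad), collapse = ", "))
  }
  comp <- chartr(valid, if (alphabet == "RNA") "UGCA" else "TGCA", s)
  paste(rev(strsplit(comp, "")[[1L]]), collapse = "")
}

#' Extract the seed region of a guide strand
#'
#' By convention the seed is guide positions 2-8 from the 5' end (a 7-mer);
#' positions 1-8 give the octamer variant. `target_match` is the reverse
#' complement of the seed, i.e. the sequence sought in mRNA 3'UTRs (written
#' 5' to 3').
#'
#' @param guide a [guide_strand] or plain sequence string
#' @param start,end 1-based inclusive seed positions; width must be 7 or 8
#' @return object of class `seed_motif`: `guide_start`, `guide_end`,
#'   `guide_subseq`, `target_match`
#' @examples
#' extract_seed("ACUGCUACGAU")
#' @export
extract_seed <- function(guide, start = 2L, end = 8L) {
  seq <- as_guide_seq(guide)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end > nchar(seq)) {
    stop("seed positions out of range for a ", nchar(seq), " nt guide")
  }
  width <- end - start + 1L
  if (!width %in% c(7L, 8L)) {
    stop("seed width must be 7 or 8 nt, got ", width)
  }
  sub <- substr(seq, start, end)
  structure(
    list(
      guide_start = start,
      guide_end = end,
      guide_subseq = sub,
      target_match = reverse_complement(sub)
    ),
    class = "seed_motif"
  )
}

#' @export
print.seed_motif <- function(x, ...) {
  cat(sprintf("Seed motif (guide positions %d-%d): %s; target match 5'-%s-3'\n",
              x$guide_start, x$guide_end, x$guide_subseq, x$target_match))
  invisible(x)
}

#' Scan a sequence for seed-complement matches
#'
#' Finds every occurrence (including overlapping ones) of the motif's
#' `target_match` in a 3'UTR sequence. Input is normalized (uppercase,
#' T to U); ambiguity codes such as N never match.
#'
#' @param utr_seq a single UTR sequence string
#' @param motif a [seed_motif], or a plain target-side motif string
#' @return integer vector of 0-based start offsets (possibly empty)
#' @examples
#' scan_sequence("AAGUAGCAGAA", extract_seed("ACUGCUACGAU"))
#' @export
scan_sequence <- function(utr_seq, motif) {
  pat <- if (inherits(motif, "seed_motif")) motif$target_match
         else normalize_rna(motif)
  s <- normalize_rna(utr_seq)
  if (nchar(s) < nchar(pat) || nchar(s) == 0L) return(integer(0))
  # BString matching is literal: N etc. never match A/C/G/U, overlaps included
  m <- Biostrings::matchPattern(Biostrings::BString(pat), Biostrings::BString(s))
  as.integer(Biostrings::start(m)) - 1L
}

check_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seen_header <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) { seen_header <- TRUE; next }
    if (!seen_header) {
      stop("unparseable FASTA at line ", i,
           ": sequence data before any '>' header")
    }
    if (grepl("[^A-Za-z.*-]", ln)) {
      stop("unparseable FASTA at line ", i, ": invalid sequence characters")
    }
  }
  if (!seen_header) stop("unparseable FASTA at line 1: no '>' header found")
  invisible(TRUE)
}

read_utr_sequences <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      is.null(names(x))) {
    check_fasta_lines(x)
    set <- Biostrings::readBStringSet(x)
    stats::setNames(as.character(set),
                    sub("\\s.*$", "", names(set)))
  } else if (is.character(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("UTR sequences must be named (or give a FASTA path)")
    }
    x
  } else {
    stop("utrs must be a FASTA path or a named character vector")
  }
}

#' Classify a 3'UTR set by seed match
#'
#' Scans every transcript's 3'UTR for the seed complement of the given guide
#' and labels transcripts as seed-matched (SM, >= 1 match) or non-SM.
#' `mode = "7mer"` uses guide positions 2-8; `"8mer"` uses 1-8.
#'
#' @param utrs a FASTA path or a named character vector of UTR sequences
#'   (unique ids required)
#' @param guide a [guide_strand] or plain guide sequence
#' @param mode `"7mer"` (default) or `"8mer"`
#' @return object of class `seed_classification`: `$classification`
#'   (data.frame with `transcript_id`, `is_sm`, `match_count`,
#'   `match_offsets` comma-joined 0-based), `$summary` (`n_sm`, `n_non_sm`),
#'   `$motif`
#' @export
classify_utr_set <- function(utrs, guide, mode = c("7mer", "8mer")) {
  mode <- match.arg(mode)
  seqs <- read_utr_sequences(utrs)
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  motif <- if (mode == "7mer") extract_seed(guide, 2L, 8L)
           else extract_seed(guide, 1L, 8L)
  subject <- Biostrings::BStringSet(vapply(seqs, normalize_rna, ""))
  hits <- Biostrings::vmatchPattern(Biostrings::BString(motif$target_match),
                                    subject)
  starts <- Biostrings::startIndex(hits)
  offs <- lapply(starts, function(s) if (is.null(s)) integer(0) else s - 1L)
  counts <- lengths(offs)
  cls <- data.frame(
    transcript_id = ids,
    is_sm = counts >= 1L,
    match_count = as.integer(counts),
    match_offsets = vapply(offs, paste, "", collapse = ","),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(
    list(
      classification = cls,
      summary = c(n_sm = sum(cls$is_sm), n_non_sm = sum(!cls$is_sm)),
      motif = motif,
      mode = mode
    ),
    class = "seed_classification"
  )
}

#' @export
print.seed_classification <- function(x, ...) {
  cat(sprintf(
    "Seed-match classification (%s, target match 5'-%s-3')\n",
    x$mode, x$motif$target_match
  ))
  cat(sprintf("  %d seed-matched (SM), %d non-seed-matched transcripts\n",
              x$summary[["n_sm"]], x$summary[["n_non_sm"]]))
  invisible(x)
}

#' Design luciferase reporter inserts for on- and off-target readouts
#'
#' The complete-match (CM) insert is the full reverse complement of the
#' guide and reports on-target cleavage. The seed-match (SM) insert carries
#' `n_repeats` tandem copies of the reverse complement of guide positions
#' 1-8 separated by random spacers, reporting seed-only (miRNA-like)
#' repression. Spacers are rejection-sampled so that (i) scanning the insert
#' with the 7-mer seed motif yields exactly `n_repeats` matches and (ii) the
#' insert shares no complementary run of 6 nt or more with the non-seed
#' region of the guide.
#'
#' @param guide a [guide_strand] or plain guide sequence
#' @param n_repeats number of tandem seed sites (default 3)
#' @param spacer_length spacer length between sites, nt
#' @param seed integer RNG seed for spacer sampling
#' @return object of class `reporter_inserts`: `cm_insert`, `sm_insert`,
#'   `n_repeats`
#' @export
design_reporter_inserts <- function(guide, n_repeats = 3L, spacer_length = 4L,
                                    seed = 1L) {
  gseq <- as_guide_seq(guide)
  if (nchar(gseq) < 9L) stop("guide too short to have a non-seed region")
  motif7 <- extract_seed(gseq, 2L, 8L)
  site <- reverse_complement(substr(gseq, 1L, 8L))
  nonseed <- substr(gseq, 9L, nchar(gseq))
  nonseed_rc <- reverse_complement(nonseed)
  ins <- with_seed(seed, {
    repeat {
      spacers <- replicate(n_repeats, random_rna(spacer_length, 0.5))
      cand <- paste0(vapply(seq_len(n_repeats),
                            function(i) paste0(site, spacers[i]), ""),
                     collapse = "")
      ok_count <- length(scan_sequence(cand, motif7)) == n_repeats
      ok_run <- !shares_run(cand, nonseed_rc, 6L)
      if (ok_count && ok_run) break
    }
    cand
  })
  structure(
    list(cm_insert = reverse_complement(gseq), sm_insert = ins,
         n_repeats = as.integer(n_repeats)),
    class = "reporter_inserts"
  )
}

#' @export
print.reporter_inserts <- function(x, ...) {
  cat("Luciferase reporter inserts\n")
  cat("  CM (full complement):", x$cm_insert, "\n")
  cat(sprintf("  SM (%d tandem seed sites): %s\n", x$n_repeats, x$sm_insert))
  invisible(x)
}

# TRUE when a and b share any common substring of length >= k
shares_run <- function(a, b, k) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  subs <- unique(substring(a, seq_len(nchar(a) - k + 1L),
                           seq.int(k, nchar(a))))
  any(vapply(subs, function(s) grepl(s, b, fixed = TRUE), TRUE))
}
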