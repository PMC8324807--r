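# Amplicon construct model: template coordinates, PAM enumeration and IUPAC
# pattern matching, and classification of the target-codon editing state.

DNA_BASES <- c("A", "C", "G", "T")

#' Codon states recognised at the target codon
#'
#' The screen places a TGG (Trp) codon at the sixth codon of the
#' counterselectable ORF. A cytosine base editor acting through the
#' complementary strand (C·G to T·A conversion) can only turn TGG into the
#' stop codons TAG, TGA or TAA; any other 3-mer observed at the codon slot is
#' classified as `OTHER` (typically a sequencing error) and never counted as
#' an editing event.
#'
#' @format Character vector of the five state labels.
#' @export
CODON_STATES <- c("UNEDITED_TGG", "EDITED_TAG", "EDITED_TGA", "EDITED_TAA",
                  "OTHER")

# codon carried by each non-OTHER state
STATE_CODONS <- c(UNEDITED_TGG = "TGG", EDITED_TAG = "TAG",
                  EDITED_TGA = "TGA", EDITED_TAA = "TAA")

IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Define an amplicon template for a randomized-PAM survival screen
#'
#' An amplicon template fixes the coordinate layout of the sequenced PCR
#' product: a constant 5' anchor, a randomized PAM slot of `pam_length`
#' bases immediately after it, and a constant 3' segment (`anchor3`) that
#' contains the target codon at a fixed offset. All coordinates are 0-based,
#' half-open; the template starts at the first base of `anchor5`.
#'
#' @param name Short identifier.
#' @param anchor5 Constant sequence immediately 5' of the PAM slot
#'   (at least 8 bases; the locator anchors on it).
#' @param anchor3 Constant sequence from the end of the PAM slot to the end of
#'   the amplicon; it must carry `reference_codon` at `codon_offset`.
#' @param pam_length Width of the randomized PAM slot (default 4).
#' @param codon_offset 0-based offset of the target codon within `anchor3`.
#' @param reference_codon Unedited target codon (default `"TGG"`); must not be
#'   a stop codon.
#' @param pam_report_strand Either `"as_template"` (report the slot 4-mer as
#'   sequenced) or `"reverse_complement"` (report its reverse complement, for
#'   constructs sequenced on the strand opposite the protospacer).
#'
#' @return An object of class `amplicon_template` with derived fields
#'   `total_length`, `pam_slot` and `codon_slot` (each `c(start, end)`,
#'   0-based half-open in template coordinates).
#' @examples
#' tpl <- default_template()
#' tpl$total_length   # 152
#' tpl$pam_slot       # c(20, 24)
#' @export
amplicon_template <- function(name, anchor5, anchor3, pam_length = 4L,
                              codon_offset = 15L, reference_codon = "TGG",
                              pam_report_strand = c("as_template",
                                                    "reverse_complement")) {
  pam_report_strand <- match.arg(pam_report_strand)
  pam_length <- as.integer(pam_length)
  codon_offset <- as.integer(codon_offset)
  .check_dna(anchor5, "anchor5")
  .check_dna(anchor3, "anchor3")
  if (pam_length < 1L)
    stop("pam_length must be a positive integer", call. = FALSE)
  if (nchar(anchor5) < 8L)
    stop("anchor5 must be at least 8 bases for reliable anchoring",
         call. = FALSE)
  if (nchar(reference_codon) != 3L)
    stop("reference_codon must be a 3-mer", call. = FALSE)
  if (reference_codon %in% c("TAA", "TAG", "TGA"))
    stop("reference_codon must encode an amino acid, not a stop",
         call. = FALSE)
  if (codon_offset < 0L || codon_offset + 3L > nchar(anchor3))
    stop("codon_offset must place the codon inside anchor3", call. = FALSE)
  if (substr(anchor3, codon_offset + 1L, codon_offset + 3L) != reference_codon)
    stop("anchor3 must carry reference_codon at codon_offset", call. = FALSE)

  pam_start <- nchar(anchor5)
  pam_end <- pam_start + pam_length
  codon_start <- pam_end + codon_offset
  structure(list(
    name = name,
    anchor5 = toupper(anchor5),
    anchor3 = toupper(anchor3),
    pam_length = pam_length,
    pam_slot = c(pam_start, pam_end),
    codon_slot = c(codon_start, codon_start + 3L),
    reference_codon = toupper(reference_codon),
    pam_report_strand = pam_report_strand,
    total_length = pam_end + nchar(anchor3)
  ), class = "amplicon_template")
}

#' @export
print.amplicon_template <- function(x, ...) {
  cat("Amplicon template '", x$name, "' (", x$total_length, " bp)\n",
      sep = "")
  cat("  PAM slot   [", x$pam_slot[1], ", ", x$pam_slot[2], ")  width ",
      x$pam_length, ", reported ", x$pam_report_strand, "\n", sep = "")
  cat("  codon slot [", x$codon_slot[1], ", ", x$codon_slot[2], ")  reference ",
      x$reference_codon, "\n", sep = "")
  invisible(x)
}

#' Default 152-bp screen template
#'
#' A synthetic stand-in for the sequenced 152-bp amplicon: a 20-base constant
#' 5' anchor, a 4-base randomized PAM slot, and a constant downstream segment
#' whose ORF carries the target TGG at its sixth codon (offset 15 from the ORF
#' start). The anchor bases themselves are synthetic — the per-PAM statistics
#' depend only on the coordinate layout, never on the literal constants — and
#' any real construct can be supplied through [amplicon_template()].
#'
#' @return An `amplicon_template` of total length 152.
#' @export
default_template <- function() {
  amplicon_template(
    name = "screen152",
    anchor5 = "TATGCCGAACGTTCTAATAA",
    anchor3 = paste0(
      "ATGGCAGATTTAGCA", "TGG",
      "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACC",
      "CCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTA"
    ),
    pam_length = 4L,
    codon_offset = 15L,
    reference_codon = "TGG",
    pam_report_strand = "as_template"
  )
}

.check_dna <- function(x, what, alphabet = DNA_BASES) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
  bad <- setdiff(strsplit(toupper(x), "")[[1]], alphabet)
  if (length(bad))
    stop(what, " contains non-ACGT characters: ",
         paste(unique(bad), collapse = ","), call. = FALSE)
  invisible(TRUE)
}

#' Enumerate all PAM k-mers
#'
#' Returns the full k-mer library over A/C/G/T in lexicographic order
#' (A < C < G < T), the canonical ordering used by every table and matrix in
#' the package. The randomized 4-mer library has `4^4 = 256` members.
#'
#' @param k k-mer length, between 1 and 8.
#' @return Character vector of length `4^k`.
#' @examples
#' length(enumerate_pams(4))  # 256
#' @export
enumerate_pams <- function(k) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k) || k < 1 || k > 8)
    stop("k must be a single integer in [1, 8]", call. = FALSE)
  k <- as.integer(k)
  grids <- rev(rep(list(DNA_BASES), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

#' Match DNA sequences against an IUPAC pattern
#'
#' @param seq Character vector of DNA strings (A/C/G/T), each the same length
#'   as `pattern`.
#' @param pattern Single IUPAC string (e.g. `"NGGN"`, `"NGCB"`).
#' @return Logical vector, `TRUE` where every base of the sequence belongs to
#'   the IUPAC class at its position.
#' @examples
#' matches_iupac("AGGT", "NGGN")  # TRUE
#' matches_iupac("TGCA", "NGCB")  # FALSE: A is not in B = {C,G,T}
#' @export
matches_iupac <- function(seq, pattern) {
  if (!is.character(pattern) || length(pattern) != 1L)
    stop("pattern must be a single string", call. = FALSE)
  pattern <- toupper(pattern)
  pat <- strsplit(pattern, "")[[1]]
  if (!all(pat %in% names(IUPAC_CLASSES)))
    stop("pattern contains non-IUPAC codes: ",
         paste(setdiff(pat, names(IUPAC_CLASSES)), collapse = ","),
         call. = FALSE)
  seq <- toupper(seq)
  if (any(nchar(seq) != length(pat)))
    stop("sequence length must equal pattern length", call. = FALSE)
  if (!length(seq)) return(logical(0))
  bad <- setdiff(unique(strsplit(paste(seq, collapse = ""), "")[[1]]),
                 DNA_BASES)
  if (length(bad))
    stop("sequences contain non-ACGT characters: ",
         paste(bad, collapse = ","), call. = FALSE)
  ok <- rep(TRUE, length(seq))
  for (i in seq_along(pat)) {
    ok <- ok & substr(seq, i, i) %in% IUPAC_CLASSES[[pat[i]]]
  }
  ok
}

#' Count k-mers matching an IUPAC pattern
#'
#' Counts the members of the full k-mer library matching the pattern, e.g. the
#' 16 NGGN members of the 256-member 4-mer library, or the single NGG class
#' that occupies 1/16 of an NNN library.
#'
#' @inheritParams matches_iupac
#' @param k k-mer length; must equal `nchar(pattern)`.
#' @return Non-negative integer count.
#' @examples
#' count_matching("NGGN", 4)  # 16
#' @export
count_matching <- function(pattern, k) {
  if (nchar(pattern) != k)
    stop("pattern length must equal k", call. = FALSE)
  sum(matches_iupac(enumerate_pams(k), pattern))
}

#' Classify the observed target codon
#'
#' Maps a 3-mer at the codon slot to its editing state: `TGG` is unedited,
#' the three stop codons reachable from TGG by C·G-to-T·A conversion
#' (`TAG`, `TGA`, `TAA`) are the edited states, and anything else — including
#' codons containing `N` — is `OTHER`.
#'
#' @param codon Character vector of 3-mers over A/C/G/T/N.
#' @return Character vector of states (see [CODON_STATES]).
#' @examples
#' classify_codon(c("TGG", "TGA", "TCG"))
#' @export
classify_codon <- function(codon) {
  codon <- toupper(codon)
  if (any(nchar(codon) != 3L))
    stop("codons must have length 3", call. = FALSE)
  out <- rep("OTHER", length(codon))
  m <- match(codon, STATE_CODONS)
  out[!is.na(m)] <- names(STATE_CODONS)[m[!is.na(m)]]
  out
}

#' Build the ground-truth amplicon sequence for a (PAM, state) genotype
#'
#' Fills the template's PAM slot with `pam` and its codon slot with the codon
#' of `state`; every other position comes from the template constants. When
#' the template reports PAMs on the opposite strand
#' (`pam_report_strand = "reverse_complement"`), `pam` is reverse complemented
#' before insertion so that extraction reports it back unchanged.
#'
#' @param template An [amplicon_template()].
#' @param pam PAM sequence of length `template$pam_length`.
#' @param state One of the non-`OTHER` entries of [CODON_STATES] (`OTHER` has
#'   no canonical sequence).
#' @return A single DNA string of length `template$total_length`.
#' @export
synthesize_amplicon <- function(template, pam, state) {
  stopifnot(inherits(template, "amplicon_template"))
  pam <- toupper(pam)
  .check_dna(pam, "pam")
  if (nchar(pam) != template$pam_length)
    stop("pam length must equal template$pam_length", call. = FALSE)
  if (!state %in% names(STATE_CODONS))
    stop("state must be one of ",
         paste(names(STATE_CODONS), collapse = ", "),
         " (OTHER has no canonical sequence)", call. = FALSE)
  slot_pam <- if (template$pam_report_strand == "reverse_complement")
    revcomp(pam) else pam
  codon <- STATE_CODONS[[state]]
  a3 <- template$anchor3
  off <- template$codon_slot[1] - template$pam_slot[2]  # codon offset in anchor3
  substr(a3, off + 1L, off + 3L) <- codon
  paste0(template$anchor5, slot_pam, a3)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings (IUPAC codes allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Unedited reference amplicon with an ambiguous PAM slot
#'
#' @param template An [amplicon_template()].
#' @return DNA string of the unedited amplicon with `N` filling the PAM slot.
#' @export
reference_amplicon <- function(template) {
  stopifnot(inherits(template, "amplicon_template"))
  paste0(template$anchor5, strrep("N", template$pam_length), template$anchor3)
}

#' Write the template's unedited reference amplicon as FASTA
#'
#' @param template An [amplicon_template()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_template_fasta <- function(template, path) {
  seqs <- Biostrings::DNAStringSet(reference_amplicon(template))
  names(seqs) <- template$name
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Serialize / deserialize an amplicon template as YAML
#'
#' The on-disk form records the constructor arguments (name, anchors, PAM
#' width, codon offset, reference codon, strand flag), so a round trip
#' reproduces the template exactly.
#'
#' @param template An [amplicon_template()].
#' @param path File path.
#' @return `write_template_yaml` returns `path` invisibly;
#'   `read_template_yaml` returns an `amplicon_template`.
#' @export
write_template_yaml <- function(template, path) {
  stopifnot(inherits(template, "amplicon_template"))
  yaml::write_yaml(list(
    name = template$name,
    anchor5 = template$anchor5,
    anchor3 = template$anchor3,
    pam_length = template$pam_length,
    codon_offset = template$codon_slot[1] - template$pam_slot[2],
    reference_codon = template$reference_codon,
    pam_report_strand = template$pam_report_strand
  ), path)
  invisible(path)
}

#' @rdname write_template_yaml
#' @export
read_template_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("name", "anchor5", "anchor3", "pam_length", "codon_offset",
            "reference_codon", "pam_report_strand")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("template file is missing fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  amplicon_template(
    name = x$name, anchor5 = x$anchor5, anchor3 = x$anchor3,
    pam_length = x$pam_length, codon_offset = x$codon_offset,
    reference_codon = x$reference_codon,
    pam_report_strand = x$pam_report_strand
  )
}
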