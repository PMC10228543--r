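# H3 tail sequence, residue labels, mutations and observability rules.

# Human H3 N-terminal tail, positions 1-36 (1-based H3 numbering).
H3_TAIL_WT <- "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVK"
H3_TAIL_LENGTH <- 36L

#' The H3 tail sequence
#'
#' Constructs the 36-residue H3 N-terminal tail, optionally with point
#' mutations applied. Numbering is 1-based H3 numbering throughout; the
#' wild-type tail carries arginine at positions 2, 8, 17 and 26.
#'
#' @param mutations character vector of mutation labels such as `"R26Q"`
#'   (from-code, position, to-code). The from-code must match the current
#'   sequence at that position.
#' @return An object of class `tail_sequence`: a list with `residues`
#'   (one-letter codes for positions 1-36) and `mutations` (a data.frame of
#'   applied substitutions).
#' @examples
#' h3_tail()
#' h3_tail(c("R2Q", "R8Q", "R17Q", "R26Q"))
#' @export
h3_tail <- function(mutations = character()) {
  obj <- structure(
    list(residues = strsplit(H3_TAIL_WT, "")[[1]],
         mutations = data.frame(position = integer(), from = character(),
                                to = character())),
    class = "tail_sequence")
  if (length(mutations)) obj <- apply_mutations(obj, mutations)
  obj
}

#' @export
print.tail_sequence <- function(x, ...) {
  cat("H3 tail (", length(x$residues), " aa): ",
      paste(x$residues, collapse = ""), "\n", sep = "")
  if (nrow(x$mutations)) {
    cat("mutations:",
        paste0(x$mutations$from, x$mutations$position, x$mutations$to,
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Parse a residue label
#'
#' Residue labels are the one-letter amino-acid code followed by the
#' position, e.g. `"T22"` or `"K36"`. When a sequence is supplied the code
#' is validated against it.
#'
#' @param label character scalar, e.g. `"T22"`.
#' @param seq optional `tail_sequence` used to validate the code.
#' @return A `residue_id`: list with `position` (integer) and `code`.
#' @examples
#' parse_residue_label("T22")
#' residue_label(22)
#' @export
parse_residue_label <- function(label, seq = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- regmatches(label, regexec("^([A-Za-z])([0-9]+)$", label))[[1]]
  if (length(m) != 3L)
    stop("malformed residue label: '", label,
         "' (expected one letter followed by an integer)")
  pos <- as.integer(m[3])
  code <- toupper(m[2])
  if (pos < 1L) stop("residue position must be >= 1: ", label)
  if (!is.null(seq)) {
    if (pos > length(seq$residues))
      stop("position ", pos, " beyond tail length ", length(seq$residues))
    if (seq$residues[pos] != code)
      stop("residue code mismatch at position ", pos, ": label says ", code,
           " but sequence has ", seq$residues[pos])
  }
  structure(list(position = pos, code = code), class = "residue_id")
}

#' @export
format.residue_id <- function(x, ...) paste0(x$code, x$position)

#' @export
print.residue_id <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @rdname parse_residue_label
#' @param position integer position, 1-based.
#' @export
residue_label <- function(position, seq = h3_tail()) {
  stopifnot(position >= 1L, position <= length(seq$residues))
  paste0(seq$residues[position], position)
}

as_residue_id <- function(x, seq = NULL) {
  if (inherits(x, "residue_id")) return(x)
  if (is.character(x)) return(parse_residue_label(x, seq))
  if (is.numeric(x)) {
    s <- if (is.null(seq)) h3_tail() else seq
    return(parse_residue_label(residue_label(as.integer(x), s), s))
  }
  stop("cannot interpret '", deparse(x), "' as a residue")
}

#' Inclusive residue count of a tail range
#'
#' The number of positions in the span `start`..`end`, counted inclusively.
#' Invisible residues inside the span (the prolines P16 and P30) are
#' counted, so e.g. the span T22-V35 counts 14 residues.
#'
#' @param start,end residue labels (e.g. `"T22"`), positions, or
#'   `residue_id` objects. `start` must not come after `end`.
#' @return integer count, `end - start + 1`.
#' @examples
#' count_residue_range("T22", "V35")  # 14
#' count_residue_range("T3", "K36")   # 34
#' @export
count_residue_range <- function(start, end) {
  s <- as_residue_id(start)
  e <- as_residue_id(end)
  if (s$position > e$position)
    stop("range start ", format(s), " comes after end ", format(e))
  e$position - s$position + 1L
}

#' Apply point mutations to a tail sequence
#'
#' @param seq a `tail_sequence`.
#' @param mutations character vector of labels such as `"R26Q"`. The
#'   from-code must match the current (possibly already mutated) sequence;
#'   a mismatch is an error naming the position, so re-applying an already
#'   applied mutation is rejected rather than silently accepted.
#' @return A new `tail_sequence`; the input is unchanged.
#' @examples
#' apply_mutations(h3_tail(), "R26Q")
#' @export
apply_mutations <- function(seq, mutations) {
  stopifnot(inherits(seq, "tail_sequence"))
  for (lab in mutations) {
    m <- regmatches(lab, regexec("^([A-Z])([0-9]+)([A-Z])$", lab))[[1]]
    if (length(m) != 4L)
      stop("malformed mutation label: '", lab,
           "' (expected from-code, position, to-code, e.g. R26Q)")
    pos <- as.integer(m[3])
    if (pos < 1L || pos > length(seq$residues))
      stop("mutation position out of range: ", lab)
    if (seq$residues[pos] != m[2])
      stop("mutation from-code mismatch at position ", pos, ": '", lab,
           "' but sequence has ", seq$residues[pos])
    seq$residues[pos] <- m[4]
    seq$mutations <- rbind(seq$mutations,
                           data.frame(position = pos, from = m[2], to = m[4]))
  }
  seq
}

# ---- construct labels -------------------------------------------------------

#' Construct labels and their mutation sets
#'
#' Constructs are named as in the mutant nomenclature `"R2Q"`,
#' `"R2/8/17/26Q"`, with `"WT"` for the unmutated tail.
#' `parse_construct()` expands a label into individual mutation labels;
#' `construct_label()` is its inverse; `mutated_positions()` returns the
#' mutated positions.
#'
#' @param label construct label, e.g. `"R26Q"` or `"R2/8/17/26Q"`.
#' @return `parse_construct()`: character vector of mutation labels
#'   (empty for `"WT"`).
#' @examples
#' parse_construct("R2/8/17/26Q")
#' construct_label(c("R2Q", "R26Q"))
#' @export
parse_construct <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  if (toupper(label) == "WT") return(character())
  m <- regmatches(label, regexec("^R([0-9]+(/[0-9]+)*)Q$", label))[[1]]
  if (length(m) == 0L)
    stop("unknown construct label: '", label,
         "' (expected WT, or arginine-to-glutamine sets like R26Q, R2/8/17/26Q)")
  pos <- as.integer(strsplit(m[2], "/", fixed = TRUE)[[1]])
  muts <- paste0("R", pos, "Q")
  # validate against the WT sequence (errors on non-arginine positions)
  apply_mutations(h3_tail(), muts)
  muts
}

#' @rdname parse_construct
#' @param mutations character vector of mutation labels.
#' @export
construct_label <- function(mutations) {
  if (!length(mutations)) return("WT")
  pos <- sort(vapply(mutations, function(l) {
    m <- regmatches(l, regexec("^([A-Z])([0-9]+)([A-Z])$", l))[[1]]
    if (length(m) != 4L || m[2] != "R" || m[4] != "Q")
      stop("construct labels cover arginine-to-glutamine mutations only; got ", l)
    as.integer(m[3])
  }, integer(1)))
  paste0("R", paste(pos, collapse = "/"), "Q")
}

#' @rdname parse_construct
#' @export
mutated_positions <- function(label) {
  muts <- parse_construct(label)
  if (!length(muts)) return(integer())
  as.integer(gsub("[^0-9]", "", muts))
}

# ---- observability rules ----------------------------------------------------

#' Observability rules for H3 tail residues
#'
#' Which tail positions carry analyzable amide peaks. A1 and the prolines
#' P16 and P30 are never visible. Beyond that, a small set of residues is
#' omitted from relaxation analysis depending on construct and KCl
#' concentration: R2 in all samples at 0 mM (and not visible at all at
#' 150 mM), L20 in WT, R2Q, R8Q and R26Q at 0 mM and in WT at 150 mM, and
#' K36 in all samples at 150 mM.
#'
#' @param construct construct label (see [parse_construct()]).
#' @param salt_mM added KCl in mM, 0 or 150.
#' @param experiment `"relaxation"` (R1/R2/hnNOE) or `"hsqc"` (shift
#'   tables); the omission lists differ (e.g. L20 is visible in HSQC
#'   spectra but too weak for relaxation analysis).
#' @return Integer vector of positions.
#' @examples
#' omitted_positions("WT", 0)
#' observable_positions("R17Q", 150)
#' @export
invisible_positions <- function() c(1L, 16L, 30L)

#' @rdname invisible_positions
#' @export
omitted_positions <- function(construct, salt_mM,
                              experiment = c("relaxation", "hsqc")) {
  experiment <- match.arg(experiment)
  salt_mM <- check_salt(salt_mM)
  mutated_positions(construct)  # validates the label
  om <- integer()
  if (experiment == "relaxation") {
    if (salt_mM == 0) {
      om <- c(om, 2L)
      if (construct %in% c("WT", "R2Q", "R8Q", "R26Q")) om <- c(om, 20L)
    } else {
      om <- c(om, 2L, 36L)
      if (construct == "WT") om <- c(om, 20L)
    }
  } else {
    if (salt_mM > 0) om <- c(om, 2L)
  }
  sort(unique(om))
}

#' @rdname invisible_positions
#' @export
observable_positions <- function(construct, salt_mM,
                                 experiment = c("relaxation", "hsqc")) {
  experiment <- match.arg(experiment)
  setdiff(seq_len(H3_TAIL_LENGTH),
          c(invisible_positions(),
            omitted_positions(construct, salt_mM, experiment)))
}

#' Doublet residues per construct
#'
#' At 0 mM KCl a construct-dependent subset of residues is observed as two
#' resolved amide peaks (attributed to NCP asymmetry); all peaks are
#' singlets at 150 mM KCl.
#'
#' @inheritParams omitted_positions
#' @return Integer vector of positions observed as doublets.
#' @export
doublet_residues <- function(construct, salt_mM) {
  salt_mM <- check_salt(salt_mM)
  mutated_positions(construct)  # validates the label
  if (salt_mM > 0) return(integer())
  switch(construct,
         "WT" = c(2L, 36L),
         "R2Q" = 36L,
         "R8Q" = c(2L, 3L, 5L, 36L),
         "R17Q" = c(2L, 5L, 6L, 8L, 9L, 20L, 36L),
         "R26Q" = c(2L, 5L, 6L, 8L),
         integer())
}

check_salt <- function(salt_mM) {
  stopifnot(is.numeric(salt_mM), length(salt_mM) == 1L)
  if (!salt_mM %in% c(0, 150))
    stop("salt condition must be 0 or 150 mM KCl, got ", salt_mM)
  salt_mM
}

missing_reason <- function(position, construct, salt_mM,
                           experiment = "relaxation") {
  if (position %in% invisible_positions()) return("invisible")
  if (position %in% omitted_positions(construct, salt_mM, experiment))
    return("omitted")
  "not-observed"
}
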