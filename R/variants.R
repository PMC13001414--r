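## The 20 standard one-letter amino-acid codes, alphabetical.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Wild-type mitochondrial localization peptide studied throughout the
## package documentation and demos: the N-terminal 15-mer of the androgen
## receptor.
MLP_WT <- "MEVQLGLGRVYPRPP"

#' Construct a validated peptide sequence
#'
#' Sequences are stored upper-case and restricted to the 20 standard
#' one-letter amino-acid codes. A minimum length of 3 is enforced because
#' every dihedral-based analysis in the package operates on interior
#' residues (positions 2..L-1).
#'
#' @param sequence one-letter amino-acid string (case-insensitive).
#' @param label text identifier attached to the sequence.
#' @return an object of class `peptide_sequence` with elements
#'   `sequence` (string), `residues` (character vector) and `label`.
#' @export
#' @examples
#' peptide_sequence("MEVQLGLGRVYPRPP", "MLP_wt")
peptide_sequence <- function(sequence, label = "peptide") {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  seq <- toupper(gsub("[[:space:]]", "", sequence))
  res <- strsplit(seq, "")[[1]]
  if (length(res) < 3L)
    stop("peptide must have at least 3 residues for dihedral analysis, got ",
         length(res))
  bad <- setdiff(unique(res), AA_STANDARD)
  if (length(bad))
    stop("non-standard residue code(s): ", paste(bad, collapse = ", "))
  structure(list(sequence = seq, residues = res, label = label),
            class = "peptide_sequence")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat(sprintf("<peptide_sequence> %s (%d aa): %s\n",
              x$label, length(x$residues), x$sequence))
  invisible(x)
}

#' @export
length.peptide_sequence <- function(x) length(x$residues)

#' Build the complete single-position substitution panel
#'
#' Given a wild-type peptide and a 1-based position, returns the panel of
#' 20 sequences: the wild type plus the 19 variants obtained by replacing
#' the residue at `position` with each other standard amino acid. Members
#' are ordered wild type first, then alphabetically by the substituted
#' residue, and labelled `<prefix>_wt` / `<prefix>_<wtAA><pos><newAA>`
#' (e.g. `MLP_E2A`).
#'
#' @param wild_type a `peptide_sequence` or a plain sequence string.
#' @param position 1-based residue index to mutate.
#' @param prefix label prefix, default `"MLP"`.
#' @return an object of class `variant_panel` with elements `wild_type`,
#'   `position` and `members` (list of 20 `peptide_sequence`s).
#' @export
#' @examples
#' panel <- make_variant_panel("MEVQLGLGRVYPRPP", 2)
#' length(panel$members)  # 20
make_variant_panel <- function(wild_type, position, prefix = "MLP") {
  if (is.character(wild_type))
    wild_type <- peptide_sequence(wild_type, paste0(prefix, "_wt"))
  stopifnot(inherits(wild_type, "peptide_sequence"))
  L <- length(wild_type$residues)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > L)
    stop("position ", position, " out of range 1..", L)
  wt_aa <- wild_type$residues[position]
  wt <- peptide_sequence(wild_type$sequence, paste0(prefix, "_wt"))
  subs <- setdiff(AA_STANDARD, wt_aa)  # alphabetical by construction
  members <- c(list(wt), lapply(subs, function(aa) {
    r <- wild_type$residues
    r[position] <- aa
    peptide_sequence(paste(r, collapse = ""),
                     sprintf("%s_%s%d%s", prefix, wt_aa, position, aa))
  }))
  structure(list(wild_type = wt, position = position, members = members),
            class = "variant_panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("<variant_panel> %d members, position %d (%s in wild type)\n",
              length(x$members), x$position,
              x$wild_type$residues[x$position]))
  cat("  ", paste(vapply(x$members, `[[`, "", "label"), collapse = " "), "\n")
  invisible(x)
}

#' Export a variant panel as FASTA
#'
#' One record per member; record IDs are the member labels.
#'
#' @param panel a `variant_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_fasta <- function(panel, path) {
  stopifnot(inherits(panel, "variant_panel"))
  seqs <- lapply(panel$members, function(m) strsplit(m$sequence, "")[[1]])
  seqinr::write.fasta(sequences = seqs,
                      names = vapply(panel$members, `[[`, "", "label"),
                      file.out = path, as.string = FALSE)
  invisible(path)
}

#' Tabulate a variant panel
#'
#' @param panel a `variant_panel`.
#' @return data.frame with columns `label`, `sequence`, `position`,
#'   `substitution` (`"wt"` for the wild-type row).
#' @export
panel_manifest <- function(panel) {
  stopifnot(inherits(panel, "variant_panel"))
  wt_aa <- panel$wild_type$residues[panel$position]
  data.frame(
    label = vapply(panel$members, `[[`, "", "label"),
    sequence = vapply(panel$members, `[[`, "", "sequence"),
    position = panel$position,
    substitution = vapply(panel$members, function(m) {
      aa <- m$residues[panel$position]
      if (m$sequence == panel$wild_type$sequence) "wt" else aa
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Write a variant-panel JSON manifest
#'
#' @param panel a `variant_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_json <- function(panel, path) {
  jsonlite::write_json(panel_manifest(panel), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
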