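# Grouped multiple sequence alignments: an aligned FASTA plus a sequence -> group
# label table. Group labels are free strings; nothing downstream hard-codes
# particular subfamily names.

ALN_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "B", "Z", "-")

#' Construct a grouped alignment
#'
#' A grouped alignment is a set of equal-length gapped amino-acid sequences,
#' each tagged with a group label (for example a subfamily name, or `"query"`).
#' Residues are upper-cased and `.` gap characters are normalised to `-`;
#' the ambiguity codes `X`, `B` and `Z` are retained as literal characters.
#'
#' @param sequence_ids Character vector of unique sequence identifiers.
#' @param group_labels Character vector of group labels, parallel to
#'   `sequence_ids`.
#' @param sequences Character vector of gapped sequences, parallel to
#'   `sequence_ids`; all must have identical length.
#' @return An object of class `grouped_alignment` with elements `records`
#'   (data frame of `sequence_id`, `group_label`), `sequences` (named
#'   character vector) and `length` (number of alignment columns).
#' @export
grouped_alignment <- function(sequence_ids, group_labels, sequences) {
  stopifnot(length(sequence_ids) == length(group_labels),
            length(sequence_ids) == length(sequences))
  sequence_ids <- as.character(sequence_ids)
  if (anyDuplicated(sequence_ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(sequence_ids[duplicated(sequence_ids)]), collapse = ", "))
  }
  sequences <- toupper(as.character(sequences))
  sequences <- gsub(".", "-", sequences, fixed = TRUE)
  widths <- nchar(sequences)
  if (length(widths) && length(unique(widths)) > 1L) {
    ref <- widths[[1]]
    bad <- sequence_ids[widths != ref]
    stop("ragged alignment: sequence(s) ", paste(bad, collapse = ", "),
         " differ in length from '", sequence_ids[[1]], "' (", ref, " columns)")
  }
  chars <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  illegal <- setdiff(chars, ALN_ALPHABET)
  if (length(illegal)) {
    stop("unexpected characters in alignment: ", paste(illegal, collapse = ", "))
  }
  names(sequences) <- sequence_ids
  structure(
    list(records = data.frame(sequence_id = sequence_ids,
                              group_label = as.character(group_labels),
                              stringsAsFactors = FALSE),
         sequences = sequences,
         length = if (length(widths)) widths[[1]] else 0L),
    class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  cat("grouped_alignment:", nrow(x$records), "sequences x", x$length, "columns\n")
  print(table(x$records$group_label))
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param alignment A [grouped_alignment()].
#' @return Character matrix, one row per sequence (rownames are sequence ids).
#' @export
aln_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "grouped_alignment"))
  if (!nrow(alignment$records)) return(matrix(character(), 0L, alignment$length))
  m <- do.call(rbind, strsplit(unname(alignment$sequences), "", fixed = TRUE))
  rownames(m) <- alignment$records$sequence_id
  m
}

#' Sequence ids belonging to one group
#'
#' @param alignment A [grouped_alignment()].
#' @param group Group label.
#' @return Character vector of sequence ids; errors if the group is empty.
#' @export
group_members <- function(alignment, group) {
  stopifnot(inherits(alignment, "grouped_alignment"))
  ids <- alignment$records$sequence_id[alignment$records$group_label == group]
  if (!length(ids)) {
    stop("unknown or empty group: '", group, "' (available: ",
         paste(unique(alignment$records$group_label), collapse = ", "), ")")
  }
  ids
}

#' Read a grouped alignment from aligned FASTA plus a groups table
#'
#' @param alignment_path Aligned FASTA file (amino acids; gaps `-` or `.`).
#' @param groups_path Two-column TSV with header `sequence_id`, `group_label`.
#'   Every alignment id must appear in this table.
#' @return A [grouped_alignment()].
#' @export
read_grouped_alignment <- function(alignment_path, groups_path) {
  aa <- Biostrings::readAAStringSet(alignment_path)
  ids <- sub("\\s.*$", "", names(aa))
  widths <- Biostrings::width(aa)
  if (length(unique(widths)) > 1L) {
    ref <- widths[[1]]
    bad <- ids[widths != ref]
    stop("ragged alignment in ", alignment_path, ": sequence(s) ",
         paste(bad, collapse = ", "), " differ in length")
  }
  groups <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "group_label")
  miss <- setdiff(need, names(groups))
  if (length(miss)) {
    stop("groups table ", groups_path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  absent <- setdiff(ids, groups$sequence_id)
  if (length(absent)) {
    stop("alignment id(s) missing from groups table: ",
         paste(absent, collapse = ", "))
  }
  lab <- groups$group_label[match(ids, groups$sequence_id)]
  grouped_alignment(ids, lab, as.character(aa))
}

#' Write a grouped alignment to aligned FASTA plus a groups table
#'
#' Inverse of [read_grouped_alignment()]; `read(write(x))` reproduces `x`.
#'
#' @param alignment A [grouped_alignment()].
#' @param alignment_path,groups_path Output paths.
#' @return Invisibly, `alignment`.
#' @export
write_grouped_alignment <- function(alignment, alignment_path, groups_path) {
  stopifnot(inherits(alignment, "grouped_alignment"))
  aa <- Biostrings::AAStringSet(alignment$sequences)
  Biostrings::writeXStringSet(aa, alignment_path)
  utils::write.table(alignment$records, groups_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(alignment)
}
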