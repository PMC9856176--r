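# TSV tables: protein -> arCOG assignments (one arCOG per locus, as prepared
# upstream from an orthology annotator's output) and species phenotype tables.

#' Read a locus -> arCOG assignment table
#'
#' Expects a TSV with header columns `locus_id`, `arcog_id`, `cog_category`,
#' `annotation`. An empty `arcog_id` marks an unassigned locus and is stored
#' as `NA`. One row per locus; duplicates are an error.
#'
#' @param path TSV path.
#' @return Data frame with columns `locus_id`, `arcog_id`, `cog_category`,
#'   `annotation` and logical `unassigned`.
#' @export
read_arcog_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("locus_id", "arcog_id", "cog_category", "annotation")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("arCOG table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  tab <- tab[, need]
  if (anyDuplicated(tab$locus_id)) {
    stop("duplicate locus_id in arCOG table: ",
         paste(unique(tab$locus_id[duplicated(tab$locus_id)]), collapse = ", "))
  }
  tab$arcog_id[is.na(tab$arcog_id) | tab$arcog_id == ""] <- NA_character_
  tab$unassigned <- is.na(tab$arcog_id)
  tab
}

#' Write a locus -> arCOG assignment table
#'
#' @param assignments Data frame as returned by [read_arcog_table()] (the
#'   `unassigned` column is recomputed on read and not written).
#' @param path Output TSV path.
#' @return Invisibly, `assignments`.
#' @export
write_arcog_table <- function(assignments, path) {
  out <- assignments[, c("locus_id", "arcog_id", "cog_category", "annotation")]
  out$arcog_id[is.na(out$arcog_id)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(assignments)
}

parse_boolean <- function(x, column, path) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "yes")] <- TRUE
  out[v %in% c("0", "false", "no")] <- FALSE
  if (anyNA(out)) {
    stop("unparseable boolean in column '", column, "' of ", path,
         " at data row(s): ", paste(which(is.na(out)), collapse = ", "),
         " (value(s): ", paste(unique(v[is.na(out)]), collapse = ", "), ")")
  }
  out
}

#' Read a species phenotype table
#'
#' TSV with header columns `species`, `taxon_order`, `has_cetz1`, `has_cetz2`,
#' `n_other_cetz`, `motility_reported`, `rods_reported`. Booleans accept
#' `0/1`, `true/false`, `yes/no` (case-insensitive). Absence of a reported
#' phenotype is not evidence of absence; the flags record reports only.
#'
#' @param path TSV path.
#' @return Data frame of species records.
#' @export
read_species_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("species", "taxon_order", "has_cetz1", "has_cetz2",
            "n_other_cetz", "motility_reported", "rods_reported")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("species table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  tab <- tab[, need]
  for (col in c("has_cetz1", "has_cetz2", "motility_reported", "rods_reported")) {
    tab[[col]] <- parse_boolean(tab[[col]], col, path)
  }
  tab$n_other_cetz <- as.integer(tab$n_other_cetz)
  if (anyNA(tab$n_other_cetz) && nrow(tab)) {
    stop("unparseable n_other_cetz in ", path, " at data row(s): ",
         paste(which(is.na(tab$n_other_cetz)), collapse = ", "))
  }
  tab
}

#' Write a species phenotype table
#'
#' Booleans are serialised as `1`/`0`; [read_species_table()] of the output
#' reproduces the input.
#'
#' @param records Data frame of species records.
#' @param path Output TSV path.
#' @return Invisibly, `records`.
#' @export
write_species_table <- function(records, path) {
  out <- records[, c("species", "taxon_order", "has_cetz1", "has_cetz2",
                     "n_other_cetz", "motility_reported", "rods_reported")]
  for (col in c("has_cetz1", "has_cetz2", "motility_reported", "rods_reported")) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(records)
}
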