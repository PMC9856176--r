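# Species-level co-occurrence of CetZ1/CetZ2 presence with reported motility
# and rod-shape phenotypes. Counts are raw enumeration; no significance
# testing is attached, because "not reported" is not evidence of absence.

#' Tally CetZ subfamily / phenotype co-occurrence across species
#'
#' Direct enumeration of a species phenotype table: subfamily presence
#' marginals (both, CetZ1-only, CetZ2-only, neither), phenotype marginals
#' (motility reported, rods reported) and their intersections with the
#' subfamily categories. Species without a reported phenotype contribute only
#' to the marginals they satisfy.
#'
#' @param records Data frame as from [read_species_table()].
#' @return A `venn_tally` list of counts: `n_species`, `n_both`,
#'   `n_cetz1_only`, `n_cetz2_only`, `n_neither`, `n_motile`,
#'   `n_motile_and_both`, `n_motile_and_cetz1_only`, `n_rod`,
#'   `n_rod_and_both`, `n_rod_and_cetz1_only`.
#' @export
tally_cooccurrence <- function(records) {
  both <- records$has_cetz1 & records$has_cetz2
  c1only <- records$has_cetz1 & !records$has_cetz2
  c2only <- !records$has_cetz1 & records$has_cetz2
  neither <- !records$has_cetz1 & !records$has_cetz2
  mot <- records$motility_reported
  rod <- records$rods_reported
  structure(list(
    n_species = nrow(records),
    n_both = sum(both),
    n_cetz1_only = sum(c1only),
    n_cetz2_only = sum(c2only),
    n_neither = sum(neither),
    n_motile = sum(mot),
    n_motile_and_both = sum(mot & both),
    n_motile_and_cetz1_only = sum(mot & c1only),
    n_rod = sum(rod),
    n_rod_and_both = sum(rod & both),
    n_rod_and_cetz1_only = sum(rod & c1only)),
    class = "venn_tally")
}

#' @export
print.venn_tally <- function(x, ...) {
  cat("venn_tally over", x$n_species, "species\n")
  for (nm in setdiff(names(x), "n_species")) cat(" ", nm, "=", x[[nm]], "\n")
  invisible(x)
}

#' 2x2 contingency table of two boolean species-table fields
#'
#' @param records Data frame as from [read_species_table()].
#' @param row_flag,col_flag Names of boolean columns.
#' @return 2x2 integer table with `TRUE`/`FALSE` margins; cells sum to the
#'   number of species.
#' @export
crosstab <- function(records, row_flag, col_flag) {
  for (f in c(row_flag, col_flag)) {
    if (!f %in% names(records)) stop("unknown field: ", f)
    if (!is.logical(records[[f]])) stop("field is not boolean: ", f)
  }
  table(factor(records[[row_flag]], levels = c(TRUE, FALSE)),
        factor(records[[col_flag]], levels = c(TRUE, FALSE)),
        dnn = c(row_flag, col_flag))
}
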