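# End-to-end pipeline wiring: a YAML-configurable run that produces
# discriminating-residue calls, neighbourhood occurrence/conservation/pili
# tables, a synteny table and a phenotype co-occurrence tally, plus a JSON
# manifest. Outputs are deterministic given config + inputs, and every
# table echoes the thresholds it was produced with in '#' header lines.

#' Assemble a pipeline configuration
#'
#' All stages are optional: supply alignment inputs for the consensus stage,
#' genome inputs for the neighbourhood stage, and a species table for the
#' co-occurrence stage.
#'
#' @param alignment,groups Paths for [read_grouped_alignment()].
#' @param group_a,group_b Group labels to compare.
#' @param threshold_pct Unique-score threshold (default 90; 80 is customary
#'   for family-level comparisons).
#' @param chemistry Optional chemistry-classes TSV path.
#' @param genomes List of per-genome entries, each a list with `species`,
#'   `features` (GFF3 or feature TSV), `contigs` (contig TSV; optional for
#'   GFF3), `arcogs` (assignment TSV) and `focal_locus`.
#' @param flank_bp Neighbourhood flank (default 20000).
#' @param min_presence Conservation threshold; `NULL` for majority.
#' @param regulon `NULL`, or a list with `anchor_arcogs` and optionally
#'   `accessory_arcogs`, `min_anchors`, `max_gene_gap`.
#' @param species_table Path for [read_species_table()].
#' @param seed Integer seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alignment = NULL, groups = NULL,
                            group_a = NULL, group_b = NULL,
                            threshold_pct = 90, chemistry = NULL,
                            genomes = NULL, flank_bp = 20000,
                            min_presence = NULL, regulon = NULL,
                            species_table = NULL, seed = 1L) {
  stopifnot(threshold_pct > 0, threshold_pct <= 100, flank_bp > 0)
  structure(list(alignment = alignment, groups = groups, group_a = group_a,
                 group_b = group_b, threshold_pct = threshold_pct,
                 chemistry = chemistry, genomes = genomes,
                 flank_bp = flank_bp, min_presence = min_presence,
                 regulon = regulon, species_table = species_table,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Relative paths in the file are resolved against its directory.
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  }
  for (key in c("alignment", "groups", "chemistry", "species_table")) {
    raw[[key]] <- fix(raw[[key]])
  }
  if (!is.null(raw$genomes)) {
    raw$genomes <- lapply(raw$genomes, function(g) {
      for (key in c("features", "contigs", "arcogs")) g[[key]] <- fix(g[[key]])
      g
    })
  }
  do.call(pipeline_config, raw)
}

write_tsv_with_header <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param out_dir Output directory (created if needed). Files written, per
#'   configured stage: `unique_residues.tsv`, `occurrence.tsv`,
#'   `conserved.tsv`, `pili_calls.tsv`, `synteny.tsv`, `venn.tsv` and
#'   `manifest.json`.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  outputs <- character()

  if (!is.null(config$alignment)) {
    results$unique_residues <- run_stage("consensus", {
      aln <- read_grouped_alignment(config$alignment, config$groups)
      chem <- if (is.null(config$chemistry)) chemistry_classes() else
        read_chemistry_classes(config$chemistry)
      pa <- build_consensus(aln, config$group_a)
      pb <- build_consensus(aln, config$group_b)
      calls <- call_unique_residues(unique_residue_scores(pa, pb),
                                    threshold_pct = config$threshold_pct,
                                    chemistry = chem)
      write_tsv_with_header(
        calls, file.path(out_dir, "unique_residues.tsv"),
        c(paste0("group_a=", config$group_a),
          paste0("group_b=", config$group_b),
          paste0("threshold_pct=", config$threshold_pct)))
      outputs <- c(outputs, "unique_residues.tsv")
      calls
    })
  }

  if (!is.null(config$genomes)) {
    run_stage("neighborhoods", {
      regions <- lapply(config$genomes, function(g) {
        ann <- read_annotation(g$features, contigs_path = g$contigs,
                               species = g$species)
        asn <- read_arcog_table(g$arcogs)
        annotate_region(
          extract_neighborhood(ann, g$focal_locus, config$flank_bp), asn)
      })
      occ <- tally_arcogs(regions)
      cons <- conserved_arcogs(occ, config$min_presence)
      syn <- synteny_table(regions, conserved = cons)
      write_tsv_with_header(
        occ, file.path(out_dir, "occurrence.tsv"),
        c(paste0("n_regions=", attr(occ, "n_regions")),
          paste0("flank_bp=", config$flank_bp)))
      write_tsv_with_header(
        data.frame(arcog_id = as.character(cons)),
        file.path(out_dir, "conserved.tsv"),
        c(paste0("min_presence=", attr(cons, "min_presence")),
          paste0("n_regions=", attr(occ, "n_regions"))))
      write_tsv_with_header(
        syn, file.path(out_dir, "synteny.tsv"),
        paste0("flank_bp=", config$flank_bp))
      outputs <- c(outputs, "occurrence.tsv", "conserved.tsv", "synteny.tsv")
      results$occurrence <- occ
      results$conserved <- cons
      results$synteny <- syn
      if (!is.null(config$regulon)) {
        reg <- do.call(regulon_definition, config$regulon)
        calls <- do.call(rbind, lapply(regions, function(r) {
          cl <- classify_pili_association(r, reg)
          data.frame(species = r$species, focal_locus = r$focal_locus,
                     is_pili_associated = cl$is_pili_associated,
                     n_matched = nrow(cl$matched_loci),
                     matched_loci = paste(cl$matched_loci$locus_id,
                                          collapse = ","),
                     stringsAsFactors = FALSE)
        }))
        write_tsv_with_header(
          calls, file.path(out_dir, "pili_calls.tsv"),
          c(paste0("anchors=", paste(reg$anchor_arcogs, collapse = ",")),
            paste0("min_anchors=", reg$min_anchors),
            paste0("max_gene_gap=", reg$max_gene_gap)))
        outputs <- c(outputs, "pili_calls.tsv")
        results$pili_calls <- calls
      }
      invisible(NULL)
    })
  }

  if (!is.null(config$species_table)) {
    results$venn <- run_stage("cooccurrence", {
      tally <- tally_cooccurrence(read_species_table(config$species_table))
      df <- data.frame(metric = names(unclass(tally)),
                       count = unlist(unclass(tally), use.names = FALSE))
      write_tsv_with_header(df, file.path(out_dir, "venn.tsv"))
      outputs <- c(outputs, "venn.tsv")
      tally
    })
  }

  manifest <- list(
    package = "cetzkit",
    package_version = as.character(utils::packageVersion("cetzkit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = list(threshold_pct = config$threshold_pct,
                      flank_bp = config$flank_bp,
                      min_presence = config$min_presence),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
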