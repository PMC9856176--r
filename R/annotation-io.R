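# Genome annotations: contigs (with length and declared circularity) plus gene
# features with 1-based inclusive coordinates, the GFF3 convention. Coordinates
# are never converted; any half-open arithmetic is internal.

#' Construct a genome annotation
#'
#' @param contigs Data frame with columns `contig_id`, `length_bp` and
#'   optionally `is_circular` (default `FALSE`). Circularity is declared, never
#'   guessed from the annotation.
#' @param features Data frame with columns `contig_id`, `start_bp`, `end_bp`
#'   (1-based inclusive), `strand` (`+`/`-`), `locus_id` and optionally
#'   `product`.
#' @param species Optional species name carried through neighbourhood reports.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(contigs, features, species = NA_character_) {
  contigs <- as.data.frame(contigs, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  stopifnot(all(c("contig_id", "length_bp") %in% names(contigs)),
            all(c("contig_id", "start_bp", "end_bp", "strand", "locus_id") %in%
                  names(features)))
  if (is.null(contigs$is_circular)) contigs$is_circular <- FALSE
  if (is.null(features$product)) features$product <- ""
  contigs$contig_id <- as.character(contigs$contig_id)
  contigs$length_bp <- as.integer(contigs$length_bp)
  contigs$is_circular <- as.logical(contigs$is_circular)
  features$contig_id <- as.character(features$contig_id)
  features$start_bp <- as.integer(features$start_bp)
  features$end_bp <- as.integer(features$end_bp)
  features$strand <- as.character(features$strand)
  features$locus_id <- as.character(features$locus_id)
  features$product <- as.character(features$product)

  if (anyDuplicated(contigs$contig_id)) {
    stop("duplicate contig ids: ",
         paste(unique(contigs$contig_id[duplicated(contigs$contig_id)]),
               collapse = ", "))
  }
  if (anyDuplicated(features$locus_id)) {
    stop("duplicate locus ids: ",
         paste(unique(features$locus_id[duplicated(features$locus_id)]),
               collapse = ", "))
  }
  if (!all(features$strand %in% c("+", "-"))) {
    bad <- features$locus_id[!features$strand %in% c("+", "-")]
    stop("strand must be '+' or '-' for locus: ", paste(bad, collapse = ", "))
  }
  unknown <- setdiff(features$contig_id, contigs$contig_id)
  if (length(unknown)) {
    stop("feature(s) on unknown contig(s): ", paste(unknown, collapse = ", "))
  }
  if (any(features$start_bp < 1L)) {
    stop("feature start < 1 for locus: ",
         paste(features$locus_id[features$start_bp < 1L], collapse = ", "))
  }
  if (any(features$end_bp < features$start_bp)) {
    stop("feature end < start for locus: ",
         paste(features$locus_id[features$end_bp < features$start_bp],
               collapse = ", "))
  }
  len <- contigs$length_bp[match(features$contig_id, contigs$contig_id)]
  oob <- features$end_bp > len
  if (any(oob)) {
    stop("feature exceeds contig length for locus: ",
         paste(features$locus_id[oob], collapse = ", "))
  }
  features <- features[order(features$contig_id, features$start_bp,
                             features$end_bp, features$locus_id), ,
                       drop = FALSE]
  rownames(features) <- NULL
  rownames(contigs) <- NULL
  structure(list(contigs = contigs,
                 features = features[, c("contig_id", "start_bp", "end_bp",
                                         "strand", "locus_id", "product")],
                 species = species),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation", if (!is.na(x$species)) paste0("(", x$species, ")"),
      ":", nrow(x$features), "features on", nrow(x$contigs), "contig(s)\n")
  invisible(x)
}

#' Read a genome annotation from GFF3 or the package's feature-table TSV
#'
#' GFF3 files are parsed with rtracklayer; `gene` rows are used when present,
#' otherwise `CDS` rows. Contig lengths come from `##sequence-region` pragmas
#' or, when absent, from a sidecar contig table. The TSV dialect is a feature
#' table with columns `contig_id`, `start_bp`, `end_bp`, `strand`, `locus_id`,
#' `product` plus a mandatory contig table (`contig_id`, `length_bp`,
#' `is_circular`).
#'
#' @param path GFF3 (`.gff`/`.gff3`) or feature-table TSV.
#' @param contigs_path Optional contig table TSV.
#' @param circular Character vector of contig ids to declare circular
#'   (overrides/augments the contig table's `is_circular` column).
#' @param species Optional species name.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, contigs_path = NULL, circular = character(),
                            species = NA_character_) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    ann <- read_annotation_gff3(path, contigs_path)
  } else {
    if (is.null(contigs_path)) {
      stop("feature-table TSV input requires a contig table (contigs_path)")
    }
    features <- utils::read.delim(path, stringsAsFactors = FALSE)
    contigs <- utils::read.delim(contigs_path, stringsAsFactors = FALSE)
    ann <- list(contigs = contigs, features = features)
  }
  contigs <- ann$contigs
  if (is.null(contigs$is_circular)) contigs$is_circular <- FALSE
  contigs$is_circular <- contigs$is_circular | contigs$contig_id %in% circular
  genome_annotation(contigs, ann$features, species = species)
}

read_annotation_gff3 <- function(path, contigs_path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- if (any(type == "gene")) gr[type == "gene"] else gr[type == "CDS"]
  mc <- S4Vectors::mcols(keep)
  pick <- function(...) {
    cols <- list(...)
    out <- rep(NA_character_, length(keep))
    for (col in cols) {
      if (col %in% names(mc)) {
        v <- as.character(mc[[col]])
        out[is.na(out) & !is.na(v)] <- v[is.na(out) & !is.na(v)]
      }
    }
    out
  }
  locus <- pick("locus_tag", "ID", "Name")
  if (anyNA(locus)) stop("GFF3 feature(s) without locus_tag/ID/Name in ", path)
  product <- pick("product")
  product[is.na(product)] <- ""
  features <- data.frame(
    contig_id = as.character(GenomicRanges::seqnames(keep)),
    start_bp = GenomicRanges::start(keep),
    end_bp = GenomicRanges::end(keep),
    strand = as.character(GenomicRanges::strand(keep)),
    locus_id = locus,
    product = product,
    stringsAsFactors = FALSE)
  lens <- GenomeInfoDb::seqlengths(keep)
  if (!length(lens) || anyNA(lens)) {
    # rtracklayer does not carry ##sequence-region pragmas into seqinfo
    prag <- grep("^##sequence-region", readLines(path), value = TRUE)
    if (length(prag)) {
      parts <- strsplit(trimws(prag), "\\s+")
      lens <- stats::setNames(
        vapply(parts, function(p) as.integer(p[[4]]), integer(1)),
        vapply(parts, function(p) p[[2]], character(1)))
    }
  }
  if (!is.null(contigs_path)) {
    contigs <- utils::read.delim(contigs_path, stringsAsFactors = FALSE)
  } else {
    if (!length(lens) || anyNA(lens)) {
      stop("GFF3 file ", path, " lacks ##sequence-region pragmas; ",
           "supply contig lengths via contigs_path")
    }
    contigs <- data.frame(contig_id = names(lens),
                          length_bp = unname(as.integer(lens)),
                          is_circular = FALSE, stringsAsFactors = FALSE)
  }
  list(contigs = contigs, features = features)
}

#' Write a genome annotation in the feature-table TSV dialect
#'
#' Writes `features_path` and `contigs_path` such that
#' [read_annotation()] reproduces the annotation exactly.
#'
#' @param annotation A [genome_annotation()].
#' @param features_path,contigs_path Output TSV paths.
#' @return Invisibly, `annotation`.
#' @export
write_annotation <- function(annotation, features_path, contigs_path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  utils::write.table(annotation$features, features_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(annotation$contigs, contigs_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(annotation)
}
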