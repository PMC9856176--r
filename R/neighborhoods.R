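# Fixed-flank genomic windows around focal genes, arCOG occurrence/presence
# tallies across species, conserved-gene calling, type IV pili regulon
# classification, and strand-normalised synteny tables.
#
# The window around a focal gene runs from (focal start - flank) to
# (focal end + flank): the flank is measured from the gene boundaries, not the
# midpoint. On linear contigs the window is clipped at the ends; on circular
# contigs it wraps across the origin and is represented by two intervals.
# Genes partially overlapping the window are included whole.

# Window intervals in contig coordinates. Raw (possibly out-of-range) start
# and end; returns a data.frame of 1..2 rows plus the linearisation origin.
window_intervals <- function(raw_start, raw_end, contig_length,
                             is_circular) {
  L <- contig_length
  if (!is_circular) {
    ws <- max(1, raw_start)
    we <- min(L, raw_end)
    return(list(intervals = data.frame(start = ws, end = we), origin = ws))
  }
  span <- raw_end - raw_start + 1
  if (span >= L) {
    return(list(intervals = data.frame(start = 1, end = L), origin = 1))
  }
  s <- ((raw_start - 1) %% L) + 1
  e <- ((raw_end - 1) %% L) + 1
  if (s <= e) {
    list(intervals = data.frame(start = s, end = e), origin = s)
  } else {
    list(intervals = data.frame(start = c(s, 1), end = c(L, e)), origin = s)
  }
}

overlaps_any <- function(start_bp, end_bp, intervals) {
  hit <- rep(FALSE, length(start_bp))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (start_bp <= intervals$end[i] & end_bp >= intervals$start[i])
  }
  hit
}

# Offset of a position along the (possibly wrapped) window, measured from the
# window origin.
window_offset <- function(pos, origin, contig_length, is_circular) {
  if (is_circular) ((pos - origin) %% contig_length) else (pos - origin)
}

#' Extract the gene neighbourhood around a focal gene
#'
#' @param annotation A [genome_annotation()].
#' @param focal_locus Locus id of the focal gene.
#' @param flank_bp Flank on either side of the gene, in bp (default 20000,
#'   i.e. a 40 kb window plus the gene itself).
#' @return A `neighborhood_region`: list with `species`, `focal_locus`,
#'   `contig_id`, `flank_bp`, `window` (data frame of one interval, or two
#'   when wrapping a circular origin), `is_circular`, `origin` (window start
#'   used for linearisation) and `members` (features overlapping the window,
#'   ordered along the window, with an `arcog_id` column initialised to `NA`;
#'   see [annotate_region()]).
#' @export
extract_neighborhood <- function(annotation, focal_locus, flank_bp = 20000) {
  stopifnot(inherits(annotation, "genome_annotation"), flank_bp > 0)
  feats <- annotation$features
  fi <- which(feats$locus_id == focal_locus)
  if (!length(fi)) stop("unknown focal locus: ", focal_locus)
  focal <- feats[fi, ]
  ci <- which(annotation$contigs$contig_id == focal$contig_id)
  if (!length(ci)) stop("focal locus on unknown contig: ", focal$contig_id)
  contig <- annotation$contigs[ci, ]
  win <- window_intervals(focal$start_bp - flank_bp, focal$end_bp + flank_bp,
                          contig$length_bp, contig$is_circular)
  on_contig <- feats[feats$contig_id == focal$contig_id, , drop = FALSE]
  hit <- overlaps_any(on_contig$start_bp, on_contig$end_bp, win$intervals)
  members <- on_contig[hit, , drop = FALSE]
  off <- window_offset(members$start_bp, win$origin, contig$length_bp,
                       contig$is_circular)
  members <- members[order(off, members$end_bp, members$locus_id), ,
                     drop = FALSE]
  members$arcog_id <- NA_character_
  members$arcog_annotation <- NA_character_
  rownames(members) <- NULL
  structure(list(species = annotation$species,
                 focal_locus = focal_locus,
                 contig_id = focal$contig_id,
                 flank_bp = flank_bp,
                 window = win$intervals,
                 is_circular = contig$is_circular,
                 contig_length = contig$length_bp,
                 origin = win$origin,
                 members = members),
            class = "neighborhood_region")
}

#' @export
print.neighborhood_region <- function(x, ...) {
  cat("neighborhood_region around", x$focal_locus,
      if (!is.na(x$species)) paste0("(", x$species, ")"), "\n")
  cat("  window:",
      paste(sprintf("%d..%d", x$window$start, x$window$end), collapse = " + "),
      "on", x$contig_id, if (x$is_circular) "(circular)", "\n")
  cat("  members:", nrow(x$members), "genes\n")
  invisible(x)
}

#' Label neighbourhood genes with their arCOG assignments
#'
#' Loci absent from the assignment table, or present with an empty arCOG,
#' remain explicitly unassigned (`NA`).
#'
#' @param region A [extract_neighborhood()] region.
#' @param assignments Data frame as from [read_arcog_table()].
#' @return The region with `members$arcog_id` / `members$arcog_annotation`
#'   filled in.
#' @export
annotate_region <- function(region, assignments) {
  stopifnot(inherits(region, "neighborhood_region"))
  idx <- match(region$members$locus_id, assignments$locus_id)
  region$members$arcog_id <- assignments$arcog_id[idx]
  region$members$arcog_annotation <- assignments$annotation[idx]
  n_un <- sum(is.na(region$members$arcog_id))
  if (n_un) {
    message(n_un, " of ", nrow(region$members),
            " neighbourhood gene(s) unassigned for ", region$focal_locus)
  }
  region
}

#' Tally arCOG occurrence and presence across neighbourhood regions
#'
#' For each arCOG, `occurrences` is the total number of member genes across
#' all regions (the focal gene's own arCOG included) and `presence` is the
#' number of regions containing at least one such gene. Unassigned genes are
#' counted in the `n_unassigned` attribute, not as an arCOG.
#'
#' @param regions Non-empty list of annotated regions.
#' @return An `arcog_occurrence` data frame (`arcog_id`, `occurrences`,
#'   `presence`, `annotation`), sorted by decreasing occurrences, with
#'   attributes `n_regions` and `n_unassigned`.
#' @export
tally_arcogs <- function(regions) {
  if (!length(regions)) stop("no regions supplied")
  stopifnot(all(vapply(regions, inherits, logical(1), "neighborhood_region")))
  per_region <- lapply(regions, function(r) {
    r$members$arcog_id[!is.na(r$members$arcog_id)]
  })
  all_ids <- unlist(per_region, use.names = FALSE)
  occ <- table(all_ids)
  pres <- table(unlist(lapply(per_region, unique), use.names = FALSE))
  ann <- rep(NA_character_, length(occ))
  names(ann) <- names(occ)
  for (r in regions) {
    m <- r$members[!is.na(r$members$arcog_id) &
                     !is.na(r$members$arcog_annotation), ]
    new <- setdiff(intersect(m$arcog_id, names(ann)[is.na(ann)]), character(0))
    if (length(new)) {
      ann[new] <- m$arcog_annotation[match(new, m$arcog_id)]
    }
  }
  out <- data.frame(arcog_id = names(occ),
                    occurrences = as.integer(occ),
                    presence = as.integer(pres[names(occ)]),
                    annotation = unname(ann),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$occurrences, out$arcog_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_regions") <- length(regions)
  attr(out, "n_unassigned") <- sum(vapply(regions, function(r) {
    sum(is.na(r$members$arcog_id))
  }, integer(1)))
  class(out) <- c("arcog_occurrence", "data.frame")
  out
}

#' Conserved arCOGs: those present in at least `min_presence` regions
#'
#' @param table An [tally_arcogs()] occurrence table.
#' @param min_presence Absolute region count; defaults to a majority,
#'   `ceiling(n_regions / 2)`.
#' @return Character vector of arCOG ids, sorted; the threshold used is
#'   attached as attribute `min_presence`.
#' @export
conserved_arcogs <- function(table, min_presence = NULL) {
  n <- attr(table, "n_regions")
  if (is.null(min_presence)) min_presence <- ceiling(n / 2)
  if (min_presence < 1 || min_presence > n) {
    stop("min_presence must lie in [1, ", n, "]")
  }
  out <- sort(table$arcog_id[table$presence >= min_presence])
  attr(out, "min_presence") <- min_presence
  out
}

#' Define a type IV pili regulon for cassette detection
#'
#' A regulon is anchored by the ATPase/platform gene pair (pilB/pilC) and
#' refined by accessory pilin arCOGs. The pilB arCOG in the archaeal
#' orthologous-group catalogue is arCOG01818; supply your annotation's pilC
#' arCOG id alongside it.
#'
#' @param anchor_arcogs Character vector of anchor arCOG ids (typically pilB
#'   and pilC).
#' @param accessory_arcogs Accessory (pilin) arCOG ids; defaults to the seven
#'   predicted pilin arCOGs commonly flanking archaeal type IV loci.
#' @param min_anchors Distinct anchors required for a positive call
#'   (default 2).
#' @param max_gene_gap Maximum number of consecutive non-regulon genes allowed
#'   inside the cassette run (default 3). Unassigned genes count as
#'   interruptions.
#' @return A `regulon_definition` list.
#' @export
regulon_definition <- function(anchor_arcogs,
                               accessory_arcogs = c("arCOG05787", "arCOG05789",
                                                    "arCOG03821", "arCOG03822",
                                                    "arCOG05790", "arCOG05786",
                                                    "arCOG05788"),
                               min_anchors = 2L, max_gene_gap = 3L) {
  anchor_arcogs <- unique(as.character(anchor_arcogs))
  if (min_anchors > length(anchor_arcogs)) {
    stop("min_anchors (", min_anchors, ") exceeds the number of anchors (",
         length(anchor_arcogs), ")")
  }
  structure(list(anchor_arcogs = anchor_arcogs,
                 accessory_arcogs = unique(as.character(accessory_arcogs)),
                 min_anchors = as.integer(min_anchors),
                 max_gene_gap = as.integer(max_gene_gap)),
            class = "regulon_definition")
}

#' Classify a neighbourhood region as pili-associated or not
#'
#' A region is pili-associated when it contains at least `min_anchors`
#' distinct anchor arCOGs and all regulon genes (anchors plus accessories)
#' form a single run along the region interrupted by at most `max_gene_gap`
#' consecutive non-regulon genes.
#'
#' @param region An annotated [extract_neighborhood()] region.
#' @param regulon A [regulon_definition()].
#' @return List with `is_pili_associated` (logical) and `matched_loci`
#'   (data frame `locus_id`, `arcog_id`, `role`).
#' @export
classify_pili_association <- function(region, regulon) {
  stopifnot(inherits(region, "neighborhood_region"),
            inherits(regulon, "regulon_definition"))
  m <- region$members
  is_anchor <- !is.na(m$arcog_id) & m$arcog_id %in% regulon$anchor_arcogs
  is_acc <- !is.na(m$arcog_id) & m$arcog_id %in% regulon$accessory_arcogs
  matched <- which(is_anchor | is_acc)
  matched_loci <- data.frame(
    locus_id = m$locus_id[matched],
    arcog_id = m$arcog_id[matched],
    role = ifelse(is_anchor[matched], "anchor", "accessory"),
    stringsAsFactors = FALSE)
  enough_anchors <-
    length(unique(m$arcog_id[is_anchor])) >= regulon$min_anchors
  contiguous <- TRUE
  if (length(matched) > 1L) {
    gaps <- diff(matched) - 1L
    contiguous <- all(gaps <= regulon$max_gene_gap)
  }
  list(is_pili_associated = enough_anchors && contiguous,
       matched_loci = matched_loci)
}

# Gap in bp between two gene intervals on one contig (0 when overlapping),
# wrap-aware on circular contigs.
interval_gap <- function(a_start, a_end, b_start, b_end, contig_length,
                         is_circular) {
  lin <- max(b_start - a_end, a_start - b_end, 0)
  if (!is_circular) return(lin)
  # shortest of the two ways round
  g1 <- max(b_start - a_end, a_start - b_end, 0)
  g2 <- min((b_start - a_end) %% contig_length,
            (a_start - b_end) %% contig_length)
  min(g1, g2)
}

#' Genome-wide placement of an arCOG relative to a focal region
#'
#' Classifies where (if anywhere) genes of `target_arcog` occur in a genome:
#' inside the focal neighbourhood window; elsewhere but within `flank_bp` of
#' at least `min_anchors` distinct regulon anchors (a detached regulon copy);
#' elsewhere on their own; or absent from the genome. The first matching
#' category in that order is returned.
#'
#' @param annotation A [genome_annotation()].
#' @param assignments arCOG assignment table for the genome.
#' @param target_arcog arCOG id to place.
#' @param region The focal [extract_neighborhood()] region.
#' @param regulon A [regulon_definition()].
#' @param flank_bp Distance defining "within reach of" a regulon anchor;
#'   defaults to the region's flank.
#' @return One of `"in_focal_region"`, `"elsewhere_with_regulon"`,
#'   `"elsewhere_alone"`, `"absent"`.
#' @export
genome_wide_arcog_placement <- function(annotation, assignments, target_arcog,
                                        region, regulon,
                                        flank_bp = region$flank_bp) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(region, "neighborhood_region"))
  loci <- assignments$locus_id[!is.na(assignments$arcog_id) &
                                 assignments$arcog_id == target_arcog]
  feats <- annotation$features
  targets <- feats[feats$locus_id %in% loci, , drop = FALSE]
  if (!nrow(targets)) return("absent")
  on_focal_contig <- targets$contig_id == region$contig_id
  in_window <- on_focal_contig &
    overlaps_any(targets$start_bp, targets$end_bp, region$window)
  if (any(in_window)) return("in_focal_region")
  anchor_loci <- assignments$locus_id[!is.na(assignments$arcog_id) &
                                        assignments$arcog_id %in%
                                        regulon$anchor_arcogs]
  anchors <- feats[feats$locus_id %in% anchor_loci, , drop = FALSE]
  for (i in seq_len(nrow(targets))) {
    near <- anchors[anchors$contig_id == targets$contig_id[i], , drop = FALSE]
    if (!nrow(near)) next
    ci <- match(targets$contig_id[i], annotation$contigs$contig_id)
    L <- annotation$contigs$length_bp[ci]
    circ <- annotation$contigs$is_circular[ci]
    gaps <- vapply(seq_len(nrow(near)), function(k) {
      interval_gap(targets$start_bp[i], targets$end_bp[i],
                   near$start_bp[k], near$end_bp[k], L, circ)
    }, numeric(1))
    hit <- unique(assignments$arcog_id[match(near$locus_id[gaps <= flank_bp],
                                             assignments$locus_id)])
    if (length(hit) >= regulon$min_anchors) return("elsewhere_with_regulon")
  }
  "elsewhere_alone"
}

#' Strand-normalised synteny table for a set of regions
#'
#' Each member gene is reported at a signed bp offset from the focal gene,
#' with the focal gene oriented left-to-right: for a focal gene on the minus
#' strand, offsets and strands are mirror-reflected so that downstream of the
#' focal gene is always positive and maps are comparable across species.
#' arCOGs outside the `conserved` set are collapsed to `"other"`; genes with
#' no arCOG are labelled `"unassigned"`.
#'
#' @param regions List of annotated regions.
#' @param conserved Character vector of conserved arCOG ids (see
#'   [conserved_arcogs()]); `NULL` keeps every arCOG label.
#' @return Data frame with columns `region`, `species`, `locus_id`,
#'   `offset_bp`, `strand`, `arcog_id`, `label`, `is_focal`.
#' @export
synteny_table <- function(regions, conserved = NULL) {
  stopifnot(length(regions) > 0)
  rows <- lapply(regions, function(r) {
    m <- r$members
    focal <- m[m$locus_id == r$focal_locus, ]
    pos_start <- window_offset(m$start_bp, r$origin, r$contig_length,
                               r$is_circular)
    pos_end <- pos_start + (m$end_bp - m$start_bp)
    f_start <- window_offset(focal$start_bp, r$origin, r$contig_length,
                             r$is_circular)
    f_end <- f_start + (focal$end_bp - focal$start_bp)
    if (focal$strand == "+") {
      off <- pos_start - f_start
      strand <- m$strand
    } else {
      off <- f_end - pos_end
      strand <- ifelse(m$strand == "+", "-", "+")
    }
    label <- m$arcog_id
    label[is.na(label)] <- "unassigned"
    if (!is.null(conserved)) {
      keep <- label %in% c(conserved, "unassigned")
      label[!keep] <- "other"
    }
    data.frame(region = paste0(ifelse(is.na(r$species), "region", r$species),
                               ":", r$focal_locus),
               species = r$species,
               locus_id = m$locus_id,
               offset_bp = as.integer(off),
               strand = strand,
               arcog_id = m$arcog_id,
               label = label,
               is_focal = m$locus_id == r$focal_locus,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot a synteny table as arrow maps
#'
#' @param synteny Output of [synteny_table()].
#' @return A ggplot object: one row per region, genes as segments coloured by
#'   label, the focal gene highlighted.
#' @export
plot_synteny <- function(synteny) {
  synteny$y <- as.integer(factor(synteny$region))
  ggplot2::ggplot(synteny) +
    ggplot2::geom_segment(
      ggplot2::aes(x = offset_bp,
                   xend = offset_bp + ifelse(strand == "+", 800, -800),
                   y = y, yend = y, colour = label),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      linewidth = 2) +
    ggplot2::geom_point(data = synteny[synteny$is_focal, ],
                        ggplot2::aes(x = offset_bp, y = y),
                        shape = 17, size = 2) +
    ggplot2::scale_y_continuous(breaks = seq_along(unique(synteny$region)),
                                labels = unique(synteny$region)) +
    ggplot2::labs(x = "offset from focal gene (bp)", y = NULL,
                  colour = "arCOG") +
    ggplot2::theme_minimal()
}
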