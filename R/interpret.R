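# Network interpretation: node degrees, hub nodes, hemispheric and
# macroscale-region edge classification. These tables are the
# machine-readable counterparts of circle-plot / glass-brain figures.

# Resolve an edge mask (integer indices or logical) to index form and check
# it against the atlas size.
.mask_indices <- function(mask, n_nodes) {
  ne <- n_edges(n_nodes)
  if (is.logical(mask)) {
    if (length(mask) != ne) stop("logical mask length does not match atlas")
    mask <- which(mask)
  }
  mask <- as.integer(mask)
  if (length(mask) && (min(mask) < 1L || max(mask) > ne)) {
    stop("edge index out of range for ", n_nodes, "-node atlas")
  }
  mask
}

#' Node degrees within a consensus network
#'
#' Counts, for every atlas node, the consensus edges incident to it. High
#' degree nodes — the hubs of the predictive network — head the table.
#'
#' @param mask integer edge indices (canonical order) or logical mask.
#' @param atlas a `node_atlas`.
#' @return data.frame `node_id, label, hemisphere, macroscale_region,
#'   degree`, ordered by degree (desc) then node_id (asc).
#' @export
node_degrees <- function(mask, atlas) {
  n <- nrow(atlas)
  idx <- .mask_indices(mask, n)
  pairs <- edge_pairs(n)[idx, , drop = FALSE]
  deg <- tabulate(c(pairs[, 1L], pairs[, 2L]), nbins = n)
  out <- data.frame(node_id = atlas$node_id, label = atlas$label,
                    hemisphere = atlas$hemisphere,
                    macroscale_region = atlas$macroscale_region,
                    degree = deg, stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' High-degree nodes of a degree table
#'
#' Returns the top `k` nodes by degree; ties at rank `k` are all included
#' (so the output may exceed `k` rows) and the expansion is reported via a
#' message.
#'
#' @param table a degree table from [node_degrees()].
#' @param k number of hub nodes requested (default 2, the number typically
#'   narrated per network).
#' @return the qualifying rows of `table`.
#' @export
top_nodes <- function(table, k = 2) {
  stopifnot(k >= 1)
  if (nrow(table) == 0L) return(table)
  k <- min(k, nrow(table))
  cutoff <- table$degree[k]
  out <- table[table$degree >= cutoff, , drop = FALSE]
  if (nrow(out) > k) {
    message("tie at rank ", k, ": returning ", nrow(out), " nodes")
  }
  out
}

#' Classify consensus edges by hemisphere and macroscale region
#'
#' Each edge is typed as inter-hemispheric, intra-left, intra-right, or
#' midline-involving (any endpoint without a defined hemisphere, e.g. the
#' brainstem), and annotated with the unordered pair of macroscale region
#' labels of its endpoints.
#'
#' @param mask integer edge indices or logical mask.
#' @param atlas a `node_atlas`.
#' @param sign optional network sign label (`"positive"`/`"negative"`)
#'   carried into the output.
#' @return data.frame `node_a, node_b, sign, hemispheric_type, region_a,
#'   region_b` with `region_a <= region_b` alphabetically.
#' @export
classify_edges <- function(mask, atlas, sign = NA_character_) {
  n <- nrow(atlas)
  idx <- .mask_indices(mask, n)
  pairs <- edge_pairs(n)[idx, , drop = FALSE]
  ha <- atlas$hemisphere[pairs[, 1L]]
  hb <- atlas$hemisphere[pairs[, 2L]]
  if (anyNA(ha) || anyNA(hb)) stop("atlas node lacking hemisphere")
  type <- ifelse(ha == "midline" | hb == "midline", "midline-involving",
          ifelse(ha != hb, "inter",
          ifelse(ha == "left", "intra-left", "intra-right")))
  ra <- atlas$macroscale_region[pairs[, 1L]]
  rb <- atlas$macroscale_region[pairs[, 2L]]
  swap <- ra > rb
  tmp <- ra[swap]; ra[swap] <- rb[swap]; rb[swap] <- tmp
  data.frame(node_a = pairs[, 1L], node_b = pairs[, 2L], sign = sign,
             hemispheric_type = type, region_a = ra, region_b = rb,
             stringsAsFactors = FALSE)
}

#' Summary counts for classified edges
#'
#' @param annotations output of [classify_edges()].
#' @return list of two data.frames: counts `by_type` (hemispheric type) and
#'   `by_region_pair`.
#' @export
edge_class_summary <- function(annotations) {
  by_type <- as.data.frame(table(hemispheric_type = annotations$hemispheric_type),
                           stringsAsFactors = FALSE)
  names(by_type)[2L] <- "count"
  pair <- paste(annotations$region_a, annotations$region_b, sep = "--")
  by_pair <- as.data.frame(table(region_pair = pair), stringsAsFactors = FALSE)
  names(by_pair)[2L] <- "count"
  list(by_type = by_type[order(-by_type$count), , drop = FALSE],
       by_region_pair = by_pair[order(-by_pair$count), , drop = FALSE])
}
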