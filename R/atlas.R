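# Node atlas: per-node hemisphere, macroscale region and label. The atlas is
# consumed as a table; computing a parcellation is out of scope.

.HEMISPHERES <- c("left", "right", "midline")
.MACRO_REGIONS <- c("prefrontal", "motor", "insula", "parietal", "temporal",
                    "occipital", "limbic", "cerebellum", "subcortex",
                    "brainstem")

#' Load a node atlas table
#'
#' Reads a tab-separated atlas with columns `node_id` (1-based, contiguous),
#' `hemisphere` (`left`/`right`/`midline`), `macroscale_region` (one of ten
#' bilateral macroscale regions spanning cortex, subcortex, cerebellum and
#' brainstem) and a free-text `label`.
#'
#' @param path path to a tab-separated atlas file.
#' @return a `node_atlas` data.frame ordered by `node_id`.
#' @export
load_atlas <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_node_atlas(tab)
}

#' Validate a data frame as a node atlas
#'
#' @param tab data.frame with columns `node_id`, `hemisphere`,
#'   `macroscale_region`, `label`.
#' @return the validated `node_atlas` data.frame, rows ordered by `node_id`.
#' @export
as_node_atlas <- function(tab) {
  need <- c("node_id", "hemisphere", "macroscale_region", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("atlas is missing column(s): ", paste(miss, collapse = ", "))
  }
  tab <- tab[order(tab$node_id), need, drop = FALSE]
  n <- nrow(tab)
  if (anyDuplicated(tab$node_id)) {
    stop("atlas has duplicated node_id value(s)")
  }
  if (anyNA(tab$node_id) || !identical(as.integer(tab$node_id), seq_len(n))) {
    stop("atlas node_id must be contiguous 1..", n, " with no gaps")
  }
  bad_h <- setdiff(unique(tab$hemisphere), .HEMISPHERES)
  if (length(bad_h)) {
    stop("unknown hemisphere token(s): ", paste(bad_h, collapse = ", "))
  }
  bad_r <- setdiff(unique(tab$macroscale_region), .MACRO_REGIONS)
  if (length(bad_r)) {
    stop("unknown macroscale_region token(s): ", paste(bad_r, collapse = ", "))
  }
  tab$node_id <- as.integer(tab$node_id)
  rownames(tab) <- NULL
  class(tab) <- c("node_atlas", "data.frame")
  tab
}

#' Write a node atlas to a tab-separated file
#'
#' @param atlas a `node_atlas`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build the default 368-node whole-brain atlas
#'
#' Constructs a synthetic stand-in for a 368-node functional whole-brain
#' parcellation: 164 left-hemisphere and 163 right-hemisphere cortical nodes
#' spread over seven cortical macroscale regions, 7 subcortical and 13
#' cerebellar nodes per hemisphere, and one midline brainstem node. Labels
#' are generated from hemisphere and region; they carry no anatomical claim
#' beyond the region assignment.
#'
#' @return a `node_atlas` with 368 nodes and ten macroscale regions.
#' @export
build_default_atlas <- function() {
  # Cortical nodes per region; left sums to 164, right to 163.
  cortex_left  <- c(prefrontal = 40, motor = 21, insula = 7, parietal = 25,
                    temporal = 30, occipital = 21, limbic = 20)
  cortex_right <- c(prefrontal = 40, motor = 21, insula = 7, parietal = 25,
                    temporal = 30, occipital = 20, limbic = 20)
  rows <- list()
  add <- function(hemi, region, k) {
    if (k == 0) return(NULL)
    pre <- switch(hemi, left = "L", right = "R", midline = "M")
    data.frame(hemisphere = hemi, macroscale_region = region,
               label = sprintf("%s_%s_%02d", pre, region, seq_len(k)),
               stringsAsFactors = FALSE)
  }
  for (r in names(cortex_left))  rows[[length(rows) + 1L]] <- add("left", r, cortex_left[[r]])
  for (r in names(cortex_right)) rows[[length(rows) + 1L]] <- add("right", r, cortex_right[[r]])
  rows[[length(rows) + 1L]] <- add("left", "subcortex", 7)
  rows[[length(rows) + 1L]] <- add("right", "subcortex", 7)
  rows[[length(rows) + 1L]] <- add("left", "cerebellum", 13)
  rows[[length(rows) + 1L]] <- add("right", "cerebellum", 13)
  rows[[length(rows) + 1L]] <- add("midline", "brainstem", 1)
  tab <- do.call(rbind, rows)
  tab <- cbind(node_id = seq_len(nrow(tab)), tab)
  as_node_atlas(tab)
}

#' Load the atlas fixture shipped with the package
#'
#' @return the default 368-node `node_atlas` read from `inst/extdata`.
#' @export
default_atlas <- function() {
  path <- system.file("extdata", "atlas_368_synthetic.tsv",
                      package = "moodcpm", mustWork = TRUE)
  load_atlas(path)
}
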