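#' Read a combed-fiber interval table
#'
#' Fibers live on a per-fiber coordinate axis (kb); the interchange format
#' is BED6 with the fiber id in the chrom column and the `name` column
#' equal to `total` (the full fiber extent) or `replicated` (a
#' biotin-labelled sub-interval).
#'
#' @param path BED6 path.
#' @return Tibble with `fiber_id`, `start`, `end`, `type`.
#' @export
read_fibers <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(raw) < 4) gp_stop("fiber BED needs >= 4 columns")
  tibble(fiber_id = as.character(raw[[1]]),
         start = as.numeric(raw[[2]]),
         end = as.numeric(raw[[3]]),
         type = as.character(raw[[4]]))
}

#' Per-fiber replication extent
#'
#' The replication extent of a fiber is the fraction of its total length
#' covered by replicated (label-incorporating) segments, after merging
#' overlapping segments. Splitting a replicated interval into adjacent
#' pieces does not change the result.
#'
#' @param fibers Tibble with columns `fiber_id`, `start`, `end`, `type`
#'   (`total` / `replicated`), e.g. from [read_fibers()].
#' @return Tibble with `fiber_id`, `total_length`, `replicated_length`,
#'   `extent` (in `[0, 1]`).
#' @export
replication_extent <- function(fibers) {
  totals <- fibers |> filter(.data$type == "total")
  if (any(duplicated(totals$fiber_id))) {
    gp_stop("multiple 'total' intervals for fiber ",
            totals$fiber_id[duplicated(totals$fiber_id)][1])
  }
  if (any(totals$end <= totals$start)) {
    gp_stop("fiber with nonpositive total length: ",
            totals$fiber_id[which(totals$end <= totals$start)[1]])
  }
  reps <- fibers |> filter(.data$type == "replicated")
  bad <- !reps$fiber_id %in% totals$fiber_id
  if (any(bad)) gp_stop("replicated segment for unknown fiber ",
                        reps$fiber_id[which(bad)[1]])
  ti <- match(reps$fiber_id, totals$fiber_id)
  outside <- reps$start < totals$start[ti] | reps$end > totals$end[ti]
  if (any(outside)) {
    gp_stop("replicated interval outside fiber ",
            reps$fiber_id[which(outside)[1]])
  }
  merged_len <- if (nrow(reps)) {
    reps |>
      group_by(.data$fiber_id) |>
      summarise(replicated_length = merged_length(.data$start, .data$end),
                .groups = "drop")
  } else {
    tibble(fiber_id = character(), replicated_length = numeric())
  }
  totals |>
    mutate(total_length = .data$end - .data$start) |>
    left_join(merged_len, by = "fiber_id") |>
    mutate(replicated_length = dplyr::coalesce(.data$replicated_length, 0),
           extent = .data$replicated_length / .data$total_length) |>
    select(all_of(c("fiber_id", "total_length", "replicated_length",
                    "extent")))
}

# Total length of the union of [start, end) intervals.
merged_length <- function(start, end) {
  o <- order(start)
  start <- start[o]
  end <- end[o]
  tot <- 0
  cur_s <- start[1]
  cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) {
      cur_e <- max(cur_e, end[i])
    } else {
      tot <- tot + (cur_e - cur_s)
      cur_s <- start[i]
      cur_e <- end[i]
    }
  }
  tot + (cur_e - cur_s)
}
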