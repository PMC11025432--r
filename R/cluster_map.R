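#' Construct and validate a disease-to-cluster map
#'
#' A cluster map is a many-to-one partition of diseases into clusters: every
#' disease belongs to exactly one cluster, every cluster contains at least one
#' disease. The reference analysis uses 212 long-term conditions partitioned
#' into 15 clusters; any sizes satisfying the partition property are accepted.
#'
#' @param x A data frame with columns `disease_id`, `disease_name`,
#'   `cluster_id`, `cluster_name` (one row per disease).
#' @return A tibble of class `cluster_map` with the four columns coerced to
#'   character, plus attributes `n_diseases` and `n_clusters`.
#' @examples
#' cm <- cluster_map(data.frame(
#'   disease_id = c("d1", "d2", "d3"), disease_name = c("D1", "D2", "D3"),
#'   cluster_id = c("cA", "cA", "cB"), cluster_name = c("A", "A", "B")
#' ))
#' n_clusters(cm)
#' @export
cluster_map <- function(x) {
  required <- c("disease_id", "disease_name", "cluster_id", "cluster_name")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "cluster map is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "mltc_format_error")
  }
  if (nrow(x) == 0) {
    abort("cluster map has no rows", class = "mltc_format_error")
  }
  out <- as_tibble(x)[required]
  out <- mutate(out, across(all_of(required), as.character))
  dup <- out$disease_id[duplicated(out$disease_id)]
  if (length(dup) > 0) {
    abort(paste0(
      "partition violation: disease(s) mapped more than once: ",
      paste(unique(dup), collapse = ", ")
    ), class = "mltc_partition_error")
  }
  structure(out,
    class = c("cluster_map", class(out)),
    n_diseases = nrow(out),
    n_clusters = length(unique(out$cluster_id))
  )
}

#' Number of diseases / clusters in a cluster map
#' @param map A [cluster_map()].
#' @return An integer count.
#' @export
n_diseases <- function(map) attr(map, "n_diseases")

#' @rdname n_diseases
#' @export
n_clusters <- function(map) attr(map, "n_clusters")

#' Read or write a cluster map as CSV
#'
#' The file format is comma-separated UTF-8 with a header row naming the four
#' columns `disease_id,disease_name,cluster_id,cluster_name`.
#'
#' @param path Path to a CSV file.
#' @return `read_cluster_map()` returns a validated [cluster_map()];
#'   `write_cluster_map()` returns `path` invisibly.
#' @export
read_cluster_map <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mltc_format_error")
  }
  x <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character())),
    error = function(e) abort(paste0("cannot parse cluster map: ", conditionMessage(e)),
                              class = "mltc_format_error")
  )
  cluster_map(x)
}

#' @rdname read_cluster_map
#' @param map A [cluster_map()].
#' @export
write_cluster_map <- function(map, path) {
  stopifnot(inherits(map, "cluster_map"))
  readr::write_csv(as_tibble(unclass_map(map)), path)
  invisible(path)
}

unclass_map <- function(map) {
  attr(map, "n_diseases") <- NULL
  attr(map, "n_clusters") <- NULL
  class(map) <- setdiff(class(map), "cluster_map")
  map
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf(
    "<cluster_map> %d diseases in %d clusters\n",
    n_diseases(x), n_clusters(x)
  ))
  NextMethod()
}
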