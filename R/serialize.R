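# Plain-text serialization: fuzzy networks and phantoms as JSON (masks
# run-length encoded), training datasets as CSV.

#' Write / read a fuzzy network as JSON
#'
#' @param net A [fuzzy_network()].
#' @param path File path.
#' @return `read_network_json` returns the network; `write_network_json`
#'   returns `path` invisibly.
#' @export
write_network_json <- function(net, path) {
  obj <- list(
    target = net$target,
    premise = list(a = net$a, b = net$b),
    consequents = net$consequents,
    rule_table = net$rule_table
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fuzzy_network(
    premise = list(a = matrix(obj$premise$a, 3, 2),
                   b = matrix(obj$premise$b, 3, 2)),
    consequents = matrix(obj$consequents, 8, 4),
    rule_table = matrix(obj$rule_table, 8, 3,
                        dimnames = list(paste0("R", 1:8), INPUTS)),
    target = if (is.null(obj$target)) NA_character_ else obj$target
  )
}

rle_encode <- function(mask) {
  r <- rle(as.logical(mask))
  list(lengths = r$lengths, first = r$values[1])
}

rle_decode <- function(enc, grid_shape) {
  vals <- rep(c(enc$first, !enc$first), length.out = length(enc$lengths))
  matrix(inverse.rle(list(lengths = enc$lengths, values = vals)),
         grid_shape[1], grid_shape[2])
}

#' Write / read a phantom as JSON (run-length-encoded masks)
#'
#' @param phantom A `phantom`.
#' @param path File path.
#' @return `read_phantom_json` returns the phantom; the writer returns `path`
#'   invisibly.
#' @export
write_phantom_json <- function(phantom, path) {
  obj <- list(
    grid_shape = phantom$grid_shape,
    spacing = phantom$spacing,
    roles = as.list(phantom$roles),
    geometry = phantom$geometry,
    nt_includes_all_body = phantom$nt_includes_all_body,
    masks = lapply(phantom$masks, rle_encode)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_phantom_json
#' @export
read_phantom_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gs <- as.integer(obj$grid_shape)
  masks <- lapply(obj$masks, function(enc) {
    rle_decode(list(lengths = enc$lengths, first = enc$first), gs)
  })
  ph <- new_phantom(gs, obj$spacing, masks, unlist(obj$roles), obj$geometry,
                    isTRUE(obj$nt_includes_all_body))
  validate_phantom(ph)
  ph
}

#' Write a training dataset to CSV
#'
#' @param samples Tibble from [build_dataset()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(samples, path) {
  readr::write_csv(samples, path)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
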