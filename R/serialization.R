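# JSON serialization for cellular contexts, fluctuation specs and wired
# circuits, used by the command-line interface.

#' Read / write a cellular context as JSON
#'
#' @param path JSON file path.
#' @return `read_context()` returns a [cell_context()].
#' @export
read_context <- function(path) {
  if (!file.exists(path))
    gt_stop(sprintf("context file not found: %s", path), "gt_parse_error")
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    gt_stop(sprintf("malformed context JSON: %s",
                                    conditionMessage(e)), "gt_parse_error"))
  do.call(cell_context, as.list(raw))
}

#' @rdname read_context
#' @param context A [cell_context()].
#' @export
write_context <- function(context, path) {
  jsonlite::write_json(unclass(context), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read / write a wired transistor circuit as JSON
#'
#' The file holds the three inline component definitions (`c1`, `c2`,
#' `c3`), the cellular `context` and the `fluctuations` specification.
#'
#' @param path JSON file path.
#' @return `read_circuit()` returns a [transistor_circuit()].
#' @export
read_circuit <- function(path) {
  if (!file.exists(path))
    gt_stop(sprintf("circuit file not found: %s", path), "gt_parse_error")
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    gt_stop(sprintf("malformed circuit JSON: %s",
                                    conditionMessage(e)), "gt_parse_error"))
  need <- c("c1", "c2", "c3", "context")
  if (!all(need %in% names(raw)))
    gt_stop("circuit JSON needs c1, c2, c3 and context", "gt_parse_error")
  fl <- if (is.null(raw$fluctuations)) fluctuation_spec()
        else do.call(fluctuation_spec, lapply(raw$fluctuations, unlist))
  transistor_circuit(do.call(prbs_component, raw$c1),
                     do.call(prbs_component, raw$c2),
                     do.call(prbs_component, raw$c3),
                     do.call(cell_context, lapply(raw$context, unlist)),
                     fl)
}

#' @rdname read_circuit
#' @param circuit A [transistor_circuit()].
#' @export
write_circuit <- function(circuit, path) {
  payload <- list(c1 = unclass(circuit$c1), c2 = unclass(circuit$c2),
                  c3 = unclass(circuit$c3),
                  context = unclass(circuit$context),
                  fluctuations = unclass(circuit$fluctuations))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
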