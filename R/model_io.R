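#' Read or write a workflow model configuration
#'
#' Models are serialized as YAML with named sections (`catalog`, `initial`,
#' `kernel`, `masks`, `durations`, `gaps`, `overheads`, `max_visits`).
#' Numeric values are written with 15 significant digits, so a write/read
#' round trip reproduces the model at serialized precision (kernel rows are
#' re-validated to sum to 1 within 1e-8 on load).
#'
#' @param model A [workflow_model()].
#' @param path File path.
#' @return `write_workflow_model()` returns `path` invisibly;
#'   `read_workflow_model()` returns a `workflow_model`.
#' @export
write_workflow_model <- function(model, path) {
  validate_model(model)
  obj <- list(
    catalog = list(step_id = model$catalog$step_id,
                   step_name = model$catalog$step_name),
    initial = model$initial_probs,
    kernel = lapply(seq_len(nrow(model$kernel)),
                    function(i) as.double(model$kernel[i, ])),
    masks = model$occurrence_mask_probs,
    durations = list(meanlog = model$duration_meanlog,
                     sdlog = model$duration_sdlog),
    gaps = list(meanlog = model$gap_meanlog, sdlog = model$gap_sdlog),
    overheads = list(
      ct = list(meanlog = model$ct_overhead_meanlog,
                sdlog = model$ct_overhead_sdlog),
      tot = list(meanlog = model$tot_overhead_meanlog,
                 sdlog = model$tot_overhead_sdlog)),
    max_visits = model$max_visits
  )
  writeLines(yaml::as.yaml(obj, precision = 15), path)
  invisible(path)
}

#' @rdname write_workflow_model
#' @export
read_workflow_model <- function(path) {
  obj <- yaml::read_yaml(path)
  kernel <- do.call(rbind, lapply(obj$kernel, as.double))
  kernel <- kernel / rowSums(kernel)  # absorb serialization rounding
  workflow_model(
    catalog = step_catalog(obj$catalog$step_id, obj$catalog$step_name),
    initial_probs = obj$initial,
    kernel = kernel,
    occurrence_mask_probs = obj$masks,
    duration_meanlog = obj$durations$meanlog,
    duration_sdlog = obj$durations$sdlog,
    gap_meanlog = obj$gaps$meanlog, gap_sdlog = obj$gaps$sdlog,
    ct_overhead_meanlog = obj$overheads$ct$meanlog,
    ct_overhead_sdlog = obj$overheads$ct$sdlog,
    tot_overhead_meanlog = obj$overheads$tot$meanlog,
    tot_overhead_sdlog = obj$overheads$tot$sdlog,
    max_visits = obj$max_visits
  )
}
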