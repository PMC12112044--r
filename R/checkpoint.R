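# Model checkpoints: a single JSON file with a format tag, the model
# configuration and the flattened parameter vector.

CHECKPOINT_FORMAT <- "adcgnn-checkpoint-v1"

#' Save a model checkpoint
#'
#' @param model an `adcgnn_model`.
#' @param path output file (JSON).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "adcgnn_model"))
  cfg <- unclass(model$config)
  rec <- list(format = CHECKPOINT_FORMAT, config = cfg,
              theta = flatten_params(model_params(model)))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_model()].
#' @return an `adcgnn_model`.
#' @export
load_model <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(rec$format) || rec$format != CHECKPOINT_FORMAT) {
    stop("not an adcgnn checkpoint: ", path)
  }
  cfg <- rec$config
  config <- model_config(
    variant = cfg$variant, hidden_dim = cfg$hidden_dim,
    n_gat_layers = cfg$n_gat_layers, n_heads = cfg$n_heads,
    n_tasks = cfg$n_tasks, dropout = cfg$dropout,
    activation = cfg$activation, use_coords = cfg$use_coords,
    onehot_elements = cfg$onehot_elements, seed = cfg$seed
  )
  model <- make_variant(config)
  template <- model_params(model)
  theta <- as.numeric(rec$theta)
  if (length(theta) != length(flatten_params(template))) {
    stop("checkpoint parameter count does not match the configuration")
  }
  set_model_params(model, unflatten_params(template, theta))
}
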