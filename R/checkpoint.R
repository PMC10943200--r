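#' Save / load a trained summarizer
#'
#' A checkpoint directory holds a JSON manifest (`manifest.json` with the
#' training configuration, seed, vocabulary and backend class) and the
#' backend parameters (`params.rds`).
#'
#' @param fit a `goprose_fit`.
#' @param dir checkpoint directory (created if needed).
#' @return `save_summarizer()` returns `dir` invisibly;
#'   `load_summarizer()` a `goprose_fit`.
#' @export
save_summarizer <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    backend_class = class(fit$backend)[1],
    dim = fit$backend$dim,
    seed = fit$backend$seed,
    vocab = fit$backend$tokenizer$vocab,
    config = unclass(fit$config),
    best_epoch = fit$best_epoch,
    best_val_loss = fit$best_val_loss,
    history = fit$history
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(snapshot_params(fit$backend$par), file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname save_summarizer
#' @export
load_summarizer <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  tok <- structure(
    list(vocab = manifest$vocab,
         index = setNames(seq_along(manifest$vocab), manifest$vocab)),
    class = "word_tokenizer"
  )
  backend <- bow_seq2seq_backend(tok, dim = manifest$dim, seed = manifest$seed)
  restore_params(backend$par, readRDS(file.path(dir, "params.rds")))
  cfg <- do.call(training_config, manifest$config)
  structure(
    list(backend = backend,
         history = tibble::as_tibble(manifest$history),
         config = cfg,
         best_epoch = manifest$best_epoch,
         best_val_loss = manifest$best_val_loss),
    class = "goprose_fit"
  )
}
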