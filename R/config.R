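#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one validated list. The
#' defaults are tuned for the full-scale problem (572 drugs, 65
#' interaction types): restart probability `alpha = 0.8`,
#' diffusion tolerance `epsilon = 1e-9`; autoencoder lr 0.01, 80 epochs,
#' dropout 0, batch 64, per-network embedding 256, unified dimension 640;
#' predictor lr 0.001, up to 100 epochs, dropout 0.2, batch 128, hidden
#' layers 640/320/160 with early stopping. Use [benchmark_config()] for
#' dimensions matched to the bundled synthetic benchmark.
#'
#' @param alpha restart probability of the random walk, in (0,1).
#' @param epsilon L1 convergence tolerance of the walk, > 0.
#' @param mda autoencoder hyperparameters: `lr`, `epochs`, `dropout`,
#'   `batch_size`, `d_embed` (per-network embedding width),
#'   `shared_dims` (widths of the shared integration layers; the last
#'   entry is the unified embedding width `d_u`).
#' @param dnn predictor hyperparameters: `lr`, `epochs`, `dropout`,
#'   `batch_size`, `hidden` (hidden layer widths), `patience` (early
#'   stopping), `val_fraction` (held-out validation share).
#' @param operator pair aggregation operator: `"concat"`, `"inner"` or `"sum"`.
#' @param cv list with `folds`, `scene` (`"S1"`, `"S2"`, `"S3"`) and `seed`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.8,
                            epsilon = 1e-9,
                            mda = list(),
                            dnn = list(),
                            operator = "concat",
                            cv = list()) {
  mda_def <- list(lr = 0.01, epochs = 80L, dropout = 0, batch_size = 64L,
                  d_embed = 256L, shared_dims = 640L)
  dnn_def <- list(lr = 0.001, epochs = 100L, dropout = 0.2, batch_size = 128L,
                  hidden = c(640L, 320L, 160L), patience = 10L,
                  val_fraction = 0.1)
  cv_def <- list(folds = 5L, scene = "S1", seed = 1L)
  mda <- utils::modifyList(mda_def, as.list(mda))
  dnn <- utils::modifyList(dnn_def, as.list(dnn))
  cv <- utils::modifyList(cv_def, as.list(cv))
  stopifnot(alpha > 0, alpha < 1, epsilon > 0,
            mda$d_embed >= 1, all(mda$shared_dims >= 1),
            mda$dropout >= 0, mda$dropout < 1,
            dnn$dropout >= 0, dnn$dropout < 1,
            all(dnn$hidden >= 1), cv$folds >= 2)
  operator <- match.arg(operator, c("concat", "inner", "sum"))
  cv$scene <- match.arg(toupper(cv$scene), c("S1", "S2", "S3"))
  structure(list(alpha = alpha, epsilon = epsilon, mda = mda, dnn = dnn,
                 operator = operator, cv = cv),
            class = "pipeline_config")
}

#' Configuration scaled to the synthetic benchmark
#'
#' Same structure and learning settings as [pipeline_config()], with the
#' layer widths scaled to the 80-drug synthetic benchmark: per-network
#' embedding 32, unified dimension 64, predictor hidden layers 64/32,
#' batch size 64. Dimension ratios relative to the drug count mirror the
#' full-scale configuration.
#'
#' @param ... overrides forwarded to [pipeline_config()].
#' @return an object of class `pipeline_config`.
#' @export
benchmark_config <- function(...) {
  base <- list(mda = list(d_embed = 32L, shared_dims = 64L),
               dnn = list(hidden = c(64L, 32L), batch_size = 64L))
  over <- list(...)
  for (nm in names(over)) {
    if (nm %in% c("mda", "dnn", "cv") && nm %in% names(base)) {
      base[[nm]] <- utils::modifyList(base[[nm]], over[[nm]])
    } else base[[nm]] <- over[[nm]]
  }
  do.call(pipeline_config, base)
}
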