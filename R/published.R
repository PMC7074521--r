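#' Published pooled confusion matrices
#'
#' The pooled (1000-iteration) confusion matrices reported for the
#' three hybrid classifiers and the majority-voting ensemble on the
#' original 585-image chickpea set, shipped as CSV fixtures. They serve
#' as oracle inputs for the metrics module: feeding them through
#' [ccr()], [class_metrics()] and [misclassified()] reproduces every
#' printed rate.
#'
#' @param classifier `"pso"`, `"aco"`, `"hs"`, or `"mv"`.
#' @param set `"test"`, `"train"`, or `"val"` (the ensemble has `"test"`
#'   only).
#' @return an `"sv_confusion"` count matrix.
#' @examples
#' ccr(published_confusion("mv", "test"))  # 99.10
#' @export
published_confusion <- function(classifier = c("mv", "pso", "aco", "hs"),
                                set = c("test", "train", "val")) {
  classifier <- match.arg(classifier)
  set <- match.arg(set)
  if (classifier == "mv" && set != "test") {
    abort("only the test matrix is published for the ensemble.")
  }
  path <- system.file("extdata",
                      paste0("confusion_", classifier, "_", set, ".csv"),
                      package = "seedvision", mustWork = TRUE)
  read_confusion_csv(path)
}
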