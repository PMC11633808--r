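# broom-style accessors for fitted objects and confusion maps.

#' @export
tidy.aco_fit <- function(x, ...) {
  x$history
}

#' @export
glance.aco_fit <- function(x, ...) {
  last_fin <- function(v) {
    v <- v[is.finite(v)]
    if (length(v)) v[length(v)] else NA_real_
  }
  tibble(
    adversarial = x$adversarial,
    epochs = x$config$epochs,
    n_updates = nrow(x$history),
    organs = x$k,
    base_filters = x$config$base_filters,
    use_synthetic_errors = x$config$use_synthetic_errors,
    ablation = x$config$ablation,
    final_fl_g = last_fin(x$history$fl_g),
    final_fl_d = last_fin(x$history$fl_d)
  )
}

#' @export
tidy.confusion_map <- function(x, ...) {
  d <- dim(x$labels)
  tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    label = names(CONFUSION_LEVELS)[match(as.vector(x$labels),
                                          CONFUSION_LEVELS)],
    gdc_modified = as.vector(x$gdc_modified)
  )
}

#' @export
glance.confusion_map <- function(x, ...) {
  compute_metrics(x)
}
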