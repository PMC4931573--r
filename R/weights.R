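# Weight lookup with per-compound (transitions) / per-reaction overrides.
.weightFor <- function(config, category, key) {
  ov <- config@overrides
  if (nrow(ov)) {
    hit <- which(ov$category == category & ov$key == key)
    if (length(hit)) return(ov$weight[hit[1L]])
  }
  switch(category,
         endogenous = config@wWorker,
         insertion = config@wOther,
         transition = config@wTransition,
         stop("no default weight for category ", category))
}

#' @rdname WeightConfig-class
#' @param x a `WeightConfig`.
#' @export
wWorker <- function(x) x@wWorker

#' @rdname WeightConfig-class
#' @export
wOther <- function(x) x@wOther

#' @rdname WeightConfig-class
#' @export
wTransition <- function(x) x@wTransition

#' @rdname WeightConfig-class
#' @export
weightOverrides <- function(x) x@overrides
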