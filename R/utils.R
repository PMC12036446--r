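`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bao <- function(..., class = "qcbao_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

deg2rad <- function(deg) deg * pi / 180
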