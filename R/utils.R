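# internal helpers shared across modules

abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

notify <- function(fmt, ...) {
  message("surfscore: ", sprintf(fmt, ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 17 significant digits so that doubles survive a write/parse round trip
format_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g", width = -1)
  out[is.na(x)] <- "NA"
  out
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

# accepts a surfaceome_catalog object or a plain character vector of genes
as_gene_set <- function(x) {
  if (inherits(x, "surfaceome_catalog")) x$catalog else as.character(x)
}
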