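#' @keywords internal
"_PACKAGE"

# Structured log line: timestamp | stage | message. Goes to message() so it is
# suppressible and machine-greppable.
kb_log <- function(stage, ...) {
  message(sprintf("[%s] %s | %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, paste0(...)))
}

# Deterministic 31-bit seed derived from (base_seed, tag...). Used so that
# fold plans are identical across models/weights given one base seed.
derive_seed <- function(base_seed, ...) {
  parts <- c(base_seed, unlist(lapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) else x
  })))
  h <- 0
  for (p in parts) h <- (h * 7919 + as.numeric(p) * 104729) %% 2147483647
  as.integer(h) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
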