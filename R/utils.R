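# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a 32-bit hash of a character scalar; used to fingerprint configs in
# report files so outputs are traceable to their inputs
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor the byte into the low 8 bits (h may exceed the signed-int range)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, in double arithmetic:
    # split h to keep products inside the exact-double range
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

config_fingerprint <- function(params) {
  stopifnot(inherits(params, "cea_parameters"))
  fnv1a32(yaml::as.yaml(unclass_deep(params)))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("htncea_domain_error", "error")))
}

stop_validation <- function(field, ...) {
  stop(errorCondition(sprintf("invalid parameter '%s': %s", field, paste0(...)),
                      class = c("htncea_validation_error", "error")))
}
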