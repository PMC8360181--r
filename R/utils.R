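# Error conditions: every reader/operation failure carries a distinct class
# (all inherit "hd_error") so callers and tests can discriminate failure modes.
hd_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hd_error")))
}

hd_parse_error      <- function(msg) hd_abort(msg, "hd_parse_error")
hd_phase_error      <- function(msg) hd_abort(msg, "hd_phase_error")
hd_validation_error <- function(msg) hd_abort(msg, "hd_validation_error")
hd_pedigree_error   <- function(msg) hd_abort(msg, "hd_pedigree_error")
hd_model_error      <- function(msg) hd_abort(msg, "hd_model_error")
hd_config_error     <- function(msg) hd_abort(msg, "hd_config_error")
hd_sim_error        <- function(msg) hd_abort(msg, "hd_sim_error")
hd_domain_error     <- function(msg) hd_abort(msg, "hd_domain_error")
hd_refmismatch_error <- function(msg) hd_abort(msg, "hd_refmismatch_error")

# log(sum(exp(x))) without overflow; the workhorse of the exact tail sums
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)
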