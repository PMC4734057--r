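# Timestamped diagnostics on stderr: INFO for progress, WARNING for
# tolerated anomalies, ERROR for per-file failures.
aln_log <- function(level, msg) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", msg)
}

# Order-preserving parallel map over input files. Forked workers where
# available; serial otherwise. Results always come back in input order, so
# downstream output is byte-identical for any `cores`.
aln_apply <- function(X, FUN, cores = 1L) {
  cores <- max(1L, as.integer(cores))
  if (cores == 1L || .Platform$OS.type == "windows" || length(X) < 2L) {
    lapply(X, FUN)
  } else {
    parallel::mclapply(X, FUN, mc.cores = cores, mc.preschedule = TRUE)
  }
}
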