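# internal helpers shared across modules

.mrError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mrscreen_error", "error")))
}

# derive a sub-stream seed from a master seed; kept well below 2^31
.subSeed <- function(seed, k) {
  (abs(as.integer(seed)) %% 2000000L) * 1009L + as.integer(k)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# deterministic TSV writer; %.17g keeps doubles round-trippable
.writeTable <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.17g", out[[j]]))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
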