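# Internal helpers: classed conditions, seeded evaluation, deterministic table output.

pn_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "pnstage_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

pn_validation_error <- function(msg) pn_stop(msg, "pnstage_validation_error")
pn_format_error     <- function(msg) pn_stop(msg, "pnstage_format_error")
pn_io_error         <- function(msg) pn_stop(msg, "pnstage_io_error")
pn_parameter_error  <- function(msg) pn_stop(msg, "pnstage_parameter_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# All tabular output goes through one writer so runs are byte-identical.
write_tsv_det <- function(df, path) {
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) pn_io_error(sprintf("directory does not exist: %s", dirname(path)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", na = "NA")
  invisible(path)
}

read_tsv_det <- function(path) {
  if (!file.exists(path)) pn_io_error(sprintf("file not found: %s", path))
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
}

write_json_det <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

# Dense integer rank of labels: map arbitrary labels to 0..k-1 keeping -1 as noise.
densify_labels <- function(labels) {
  noise <- labels == -1L
  u <- sort(unique(labels[!noise]))
  out <- rep(-1L, length(labels))
  out[!noise] <- match(labels[!noise], u) - 1L
  names(out) <- names(labels)
  out
}
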