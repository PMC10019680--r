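# shared internal helpers: labeled TSV I/O, seed handling, tiny hashing

.writeLabeledTSV <- function(mat, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readLabeledTSV <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. All package randomness flows through this.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream addressing: map (seed, index) to a 31-bit seed so
# draws are reproducible and independently addressable.
.substreamSeed <- function(seed, index) {
  s <- (abs(as.double(seed)) * 69069 + as.double(index) * 104729 + 1) %% 2147483629
  as.integer(s)
}

# FNV-1a over a character scalar; used to stamp outputs with a config hash.
.fnv1a <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.double(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.upperTriIdx <- function(n) which(upper.tri(matrix(0, n, n), diag = TRUE))
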