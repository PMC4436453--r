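## small internal helpers shared across modules

# uppercase and DNA->RNA (T->U)
normalize_rna <- function(x) chartr("T", "U", toupper(x))

check_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("non-ACGU symbol in ", what, ": ",
         paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

# reverse complement of RNA strings (vectorised)
rna_revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# pull a sequence out of a character scalar, a record row, or a list
record_seq <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x))) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, "sequence" %in% names(x))
    return(x$sequence)
  }
  if (is.list(x) && !is.null(x$sequence)) return(x$sequence)
  if (is.character(x) && length(x) == 1L) return(unname(x))
  stop("cannot extract a sequence from object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

record_id <- function(x, default = NA_character_) {
  if (is.data.frame(x) && "id" %in% names(x)) return(x$id[1L])
  if (is.list(x) && !is.null(x$id)) return(x$id)
  if (is.character(x) && !is.null(names(x))) return(names(x)[1L])
  default
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random RNA string(s)
random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}
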