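#' Fractional identity between two A-domain pocket codes
#'
#' NRPS adenylation domains select their substrate through ten binding-pocket
#' residues, conventionally condensed into a 10-character signature (the
#' specificity code). Identity is the fraction of matching positions; the
#' unknown symbol `'-'` never matches, so an all-unknown code has identity 0
#' to everything.
#'
#' @param a,b 10-character code strings (20-letter amino-acid alphabet plus
#'   `'-'`).
#' @return Fraction in \[0, 1\].
#' @examples
#' code_identity("DAFWIGGTFK", "DAFWIGGTFK")  # 1
#' code_identity("DAFWIGGTFK", "DGFFLGVVYK")  # 0.4
#' @export
code_identity <- function(a, b) {
  if (nchar(a) != 10L || nchar(b) != 10L) {
    stop("pocket codes must be exactly 10 characters")
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca == cb & ca != "-") / 10
}

#' Predict the substrate of an A domain from its pocket code
#'
#' Nearest-neighbour lookup against a reference code table. Ties at the best
#' identity return all tied substrates; a best identity below `min_identity`
#' is an explicit no-call.
#'
#' @param code 10-character query code.
#' @param table Reference table: data.frame with columns `code` and
#'   `substrate` (default the packaged synthetic reference table).
#' @param min_identity Minimum identity for a call (default 0.8).
#' @return List with `substrate` (character vector; `NA` for a no-call) and
#'   `identity` (best identity found).
#' @examples
#' predict_substrate("DAFWIGGTFK")$substrate  # "Val"
#' @export
predict_substrate <- function(code, table = reference_code_table(),
                              min_identity = 0.8) {
  if (!nrow(table)) stop("reference code table is empty")
  ident <- vapply(table$code, code_identity, numeric(1), b = code)
  best <- max(ident)
  if (best < min_identity) {
    return(list(substrate = NA_character_, identity = best))
  }
  list(substrate = sort(unique(table$substrate[ident == best])),
       identity = best)
}

#' Packaged reference code table (synthetic)
#'
#' Constructed stand-in pocket codes, one per substrate, used for tests and
#' examples; see the shipped file's header for provenance.
#'
#' @return data.frame with columns `substrate`, `code`.
#' @export
reference_code_table <- function() {
  path <- system.file("extdata", "stachelhaus_reference_synthetic.tsv",
                      package = "nodulomics", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", colClasses = "character")
}

#' Read a cluster code table
#'
#' Reads a delimited table of A-domain codes (columns `cluster_id`, `gene`,
#' `module_index`, `code`, optional `known_substrate`).
#'
#' @param path File path; default the packaged synthetic two-cluster table
#'   (gramicidin-type reference vs britacidin-type query).
#' @return data.frame ordered by `cluster_id`, `module_index`.
#' @export
read_code_table <- function(path = system.file(
    "extdata", "stachelhaus_codes_synthetic.tsv", package = "nodulomics",
    mustWork = TRUE)) {
  tab <- utils::read.delim(path, comment.char = "#",
                           colClasses = "character")
  tab$module_index <- as.integer(tab$module_index)
  tab[order(tab$cluster_id, tab$module_index), , drop = FALSE]
}

#' Align two ordered A-domain clusters by code similarity
#'
#' Global (Needleman-Wunsch) alignment of two module-ordered code lists with
#' match score equal to [code_identity()] and a linear gap penalty.
#' Query modules aligned to gaps are "additional domains" (e.g. the two extra
#' modules a longer biosynthetic cluster carries); their substrates are
#' predicted from the reference code table.
#'
#' @param query data.frame of the query cluster (columns `module_index`,
#'   `code`), ordered by module index.
#' @param reference data.frame of the reference cluster, same layout.
#' @param gap Linear gap penalty in identity units (default 0.4).
#' @param ref_table Reference code table for substrate prediction of
#'   insertions.
#' @return List with `alignment` (data.frame `query_index`, `ref_index`
#'   (`NA` marks an insertion/deletion), `identity`), `score`, and
#'   `insertions` (data.frame `query_index`, `code`, `predicted`).
#' @export
map_domains <- function(query, reference, gap = 0.4,
                        ref_table = reference_code_table()) {
  if (!nrow(query) || !nrow(reference)) stop("empty cluster")
  qc <- query$code
  rc <- reference$code
  n <- length(qc); m <- length(rc)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1] <- -gap * (0:n)
  S[1, ] <- -gap * (0:m)
  ptr <- matrix(0L, n + 1L, m + 1L)  # 1 diag, 2 up (query gap-aligned), 3 left
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + code_identity(qc[i], rc[j])
      u <- S[i, j + 1L] - gap
      l <- S[i + 1L, j] - gap
      best <- max(d, u, l)
      S[i + 1L, j + 1L] <- best
      ptr[i + 1L, j + 1L] <- which.max(c(d, u, l))
    }
  }
  # traceback (prefer diagonal for deterministic output)
  i <- n + 1L; j <- m + 1L
  rows <- list()
  while (i > 1L || j > 1L) {
    mv <- if (i == 1L) 3L else if (j == 1L) 2L else ptr[i, j]
    if (mv == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_index = query$module_index[i - 1L],
        ref_index = reference$module_index[j - 1L],
        identity = code_identity(qc[i - 1L], rc[j - 1L]))
      i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_index = query$module_index[i - 1L],
        ref_index = NA_integer_, identity = NA_real_)
      i <- i - 1L
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        query_index = NA_integer_,
        ref_index = reference$module_index[j - 1L], identity = NA_real_)
      j <- j - 1L
    }
  }
  aln <- do.call(rbind, rev(rows))
  ins_idx <- aln$query_index[!is.na(aln$query_index) & is.na(aln$ref_index)]
  insertions <- data.frame(query_index = integer(0), code = character(0),
                           predicted = character(0))
  if (length(ins_idx)) {
    codes <- query$code[match(ins_idx, query$module_index)]
    pred <- vapply(codes, function(cd) {
      p <- predict_substrate(cd, ref_table)
      if (all(is.na(p$substrate))) "no-call"
      else paste(p$substrate, collapse = "/")
    }, character(1), USE.NAMES = FALSE)
    insertions <- data.frame(query_index = ins_idx, code = codes,
                             predicted = pred)
  }
  list(alignment = aln, score = S[n + 1L, m + 1L], insertions = insertions)
}

#' Predict the product sequence of a cluster
#'
#' Runs [predict_substrate()] on every module of a cluster, in module order.
#'
#' @param cluster data.frame with `module_index`, `code`.
#' @param ref_table Reference code table.
#' @param min_identity Minimum identity for a call (default 0.8).
#' @return data.frame `module_index`, `code`, `predicted` (slash-separated on
#'   ties, `"no-call"` below threshold), `identity`.
#' @export
cluster_predictions <- function(cluster, ref_table = reference_code_table(),
                                min_identity = 0.8) {
  cluster <- cluster[order(cluster$module_index), , drop = FALSE]
  pred <- lapply(cluster$code, predict_substrate, table = ref_table,
                 min_identity = min_identity)
  data.frame(module_index = cluster$module_index, code = cluster$code,
             predicted = vapply(pred, function(p)
               if (all(is.na(p$substrate))) "no-call"
               else paste(p$substrate, collapse = "/"), character(1)),
             identity = vapply(pred, `[[`, numeric(1), "identity"))
}
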