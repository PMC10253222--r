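#' The 16-landmark catalog
#'
#' The fixed craniofacial landmark set, in the canonical order used by every
#' coordinate table and by the per-landmark refinement models (model *i*
#' always refers to code `L(i)`).  Bilateral left/right structures (gonion,
#' inferior lateral orbital rim, porion, supraorbital incisura) are flagged
#' as mirror pairs.
#'
#' @return A data.frame with columns `code`, `abbreviation`, `description`
#'   and `mirror` (code of the contralateral landmark, or `NA`).
#' @export
#' @examples
#' landmark_catalog()$abbreviation
landmark_catalog <- function() {
  data.frame(
    code = sprintf("L%02d", 1:16),
    abbreviation = c("A", "AntNS", "LGoni", "LOrbi", "LPori", "LsupO",
                     "Mento", "Nasio", "PocEx", "PosNS", "RGoni", "ROrbi",
                     "RPori", "RsupO", "Sella", "XstaG"),
    description = c(
      "Point A", "Anterior nasal spine", "Left gonion",
      "Left inferior lateral orbital rim", "Left porion",
      "Left supra orbital incisura", "Menton", "Nasion",
      "External occipital protuberance", "Posterior nasal spine",
      "Right gonion", "Right inferior lateral orbital rim", "Right porion",
      "Right supra orbital incisura", "Center of sella turcica",
      "Top of crista galli"),
    mirror = c(NA, NA, "L11", "L12", "L13", "L14", NA, NA, NA, NA,
               "L03", "L04", "L05", "L06", NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Per-case landmark coordinate table
#'
#' @param coords 16 x 3 numeric matrix of (x, y, z) in px, rows in catalog
#'   order.
#' @param case_id character scalar.
#' @return A 16 x 3 matrix of class `landmark_table` with rownames `L01..L16`,
#'   colnames `x, y, z` and a `case_id` attribute.
#' @export
landmark_table <- function(coords, case_id) {
  coords <- as.matrix(coords)
  if (!all(dim(coords) == c(16L, 3L))) stop("format error: need 16 x 3 coordinates")
  if (any(!is.finite(coords))) stop("format error: non-finite coordinate")
  dimnames(coords) <- list(landmark_catalog()$code, c("x", "y", "z"))
  structure(coords, case_id = as.character(case_id),
            class = c("landmark_table", "matrix", "array"))
}

case_id_of <- function(table) attr(table, "case_id")

#' Read / write landmark coordinate tables
#'
#' Long-format CSV with header `case_id, code, x, y, z`, one row per
#' (case, landmark), 16 rows per case in catalog order.  Ground-truth and
#' prediction tables share this format, and `write_landmarks()` followed by
#' `read_landmarks()` round-trips decimal text exactly.
#'
#' @param path CSV file path.
#' @return `read_landmarks()`: a named list of [landmark_table()]s, one per
#'   case, in file order.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(case_id = "character"))
  need <- c("case_id", "code", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("format error: expected columns ", paste(need, collapse = ", "))
  }
  if (!all(vapply(df[c("x", "y", "z")], is.numeric, logical(1)))) {
    stop("parse error: non-numeric coordinate cell")
  }
  codes <- landmark_catalog()$code
  out <- list()
  for (id in unique(df$case_id)) {
    rows <- df[df$case_id == id, ]
    if (nrow(rows) != 16L || !setequal(rows$code, codes)) {
      stop("format error: case ", id, " does not have exactly the 16 landmarks")
    }
    rows <- rows[match(codes, rows$code), ]
    out[[id]] <- landmark_table(as.matrix(rows[, c("x", "y", "z")]), id)
  }
  out
}

#' @rdname read_landmarks
#' @param tables a list of [landmark_table()]s (or a single one).
#' @export
write_landmarks <- function(tables, path) {
  if (inherits(tables, "landmark_table")) tables <- list(tables)
  rows <- lapply(tables, function(tb) {
    data.frame(case_id = case_id_of(tb), code = rownames(tb),
               x = as.character(tb[, "x"]), y = as.character(tb[, "y"]),
               z = as.character(tb[, "z"]), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split cases into training and testing sets
#'
#' Reproducible random designation of `n_train` + `n_test` cases (the study
#' design uses 90 training and 30 testing cases).
#'
#' @param tables list of cases (any type).
#' @param n_train,n_test set sizes.
#' @param seed RNG seed for the designation.
#' @return A list with disjoint elements `train` and `test`.
#' @export
split_train_test <- function(tables, n_train = 90L, n_test = 30L, seed = 0L) {
  n <- length(tables)
  if (n_train + n_test > n) {
    stop("parameter error: ", n, " cases cannot supply ", n_train, " + ", n_test)
  }
  idx <- with_seed(seed, sample.int(n, n_train + n_test))
  list(train = tables[idx[seq_len(n_train)]],
       test = tables[idx[n_train + seq_len(n_test)]])
}

#' Inter-observer plotting gap
#'
#' Per-landmark 3D Euclidean distance between the same case plotted by two
#' observers, in px; symmetric in its arguments.
#'
#' @param a,b [landmark_table()]s for the same case.
#' @return Named numeric vector of 16 distances.
#' @export
interobserver_gap <- function(a, b) {
  stopifnot(inherits(a, "landmark_table"), inherits(b, "landmark_table"))
  if (!identical(case_id_of(a), case_id_of(b))) {
    stop("input error: tables refer to different cases")
  }
  sqrt(rowSums((unclass(a) - unclass(b))^2))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
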