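LAYER_NAMES <- c("V_d", "P_d", "P_n")

#' Construct a labelled binary bipartite matrix from a link table
#'
#' Internal constructor shared by the visitation/pollen builders and
#' [superimpose()]. Species are ordered by descending degree, ties broken by
#' label, so identical link sets always serialize identically.
#'
#' @param links data frame with columns `plant`, `pollinator`, `layer`
#'   (one of `V_d`, `P_d`, `P_n`); one row per (link, provenance tag).
#' @param name matrix identifier.
#' @return Object of class `bipartite_matrix`: a list with `name`, `plants`
#'   (row labels), `pollinators` (column labels), `cells` (0/1 integer
#'   matrix) and `layers` (named list of logical matrices marking which
#'   sampling method evidenced each link).
#' @keywords internal
new_bipartite_matrix <- function(links, name) {
  stopifnot(is.data.frame(links), nrow(links) > 0L)
  stopifnot(all(links$layer %in% LAYER_NAMES))
  pair <- unique(links[, c("plant", "pollinator")])
  plants <- sort(unique(pair$plant))
  polls <- sort(unique(pair$pollinator))
  cells <- matrix(0L, length(plants), length(polls),
                  dimnames = list(plants, polls))
  cells[cbind(match(pair$plant, plants), match(pair$pollinator, polls))] <- 1L
  # deterministic ordering: descending degree, then lexicographic label
  ro <- order(-rowSums(cells), rownames(cells))
  co <- order(-colSums(cells), colnames(cells))
  cells <- cells[ro, co, drop = FALSE]
  plants <- rownames(cells)
  polls <- colnames(cells)
  layers <- list()
  for (ly in intersect(LAYER_NAMES, unique(links$layer))) {
    sub <- links[links$layer == ly, , drop = FALSE]
    lm <- matrix(FALSE, length(plants), length(polls),
                 dimnames = list(plants, polls))
    lm[cbind(match(sub$plant, plants), match(sub$pollinator, polls))] <- TRUE
    layers[[ly]] <- lm
  }
  structure(list(name = name, plants = plants, pollinators = polls,
                 cells = cells, layers = layers),
            class = "bipartite_matrix")
}

#' @export
print.bipartite_matrix <- function(x, ...) {
  cat(sprintf("bipartite_matrix '%s': %d plants x %d pollinators, %d links (layers: %s)\n",
              x$name, length(x$plants), length(x$pollinators),
              sum(x$cells), paste(names(x$layers), collapse = "+")))
  invisible(x)
}

#' Number of links in a bipartite matrix
#' @param M a `bipartite_matrix`.
#' @return Integer link count.
#' @export
n_links <- function(M) {
  stopifnot(inherits(M, "bipartite_matrix"))
  sum(M$cells)
}

#' Link table of a bipartite matrix
#'
#' @param x a `bipartite_matrix`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return Data frame with one row per link: `plant`, `pollinator`, and
#'   `provenance` (`+`-separated tags among `V_d`, `P_d`, `P_n`).
#' @export
as.data.frame.bipartite_matrix <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  idx <- which(x$cells == 1L, arr.ind = TRUE)
  prov <- vapply(seq_len(nrow(idx)), function(r) {
    tags <- names(x$layers)[vapply(x$layers, function(lm)
      lm[idx[r, 1L], idx[r, 2L]], logical(1))]
    paste(tags, collapse = "+")
  }, character(1))
  out <- data.frame(plant = x$plants[idx[, 1L]],
                    pollinator = x$pollinators[idx[, 2L]],
                    provenance = prov, stringsAsFactors = FALSE)
  out[order(out$plant, out$pollinator), , drop = FALSE]
}

#' Build the diurnal visitation matrix
#'
#' Binary incidence from direct flower-visit observations: a link is present
#' iff at least one visit event was recorded for the (plant, pollinator)
#' pair. Repeated events collapse to a single link; every link carries the
#' `V_d` provenance tag.
#'
#' @param records validated visitation events ([as_visit_records()]).
#' @param name matrix id, default `"V_d"`.
#' @return A `bipartite_matrix`.
#' @export
build_visitation_matrix <- function(records, name = "V_d") {
  records <- as_visit_records(records)
  if (nrow(records) == 0L) stop("no visitation records", call. = FALSE)
  links <- unique(records[, c("plant", "pollinator")])
  links$layer <- "V_d"
  new_bipartite_matrix(links, name)
}

#' Build a pollen-load matrix
#'
#' Grain counts are summed per (specimen, plant); a (plant, pollinator
#' taxon) link is evidenced when at least one specimen of that taxon carries
#' at least `min_grains` grains of that plant. Links are tagged `P_d` or
#' `P_n` according to `period`.
#'
#' @param records validated pollen records ([as_pollen_records()]).
#' @param period `"diurnal"` or `"nocturnal"`; rows of the other period are
#'   ignored.
#' @param min_grains evidence threshold in grains per specimen (default 5).
#' @param name matrix id; defaults to `"P_d"`/`"P_n"` by period.
#' @return A `bipartite_matrix`.
#' @export
build_pollen_matrix <- function(records, period = c("diurnal", "nocturnal"),
                                min_grains = 5L, name = NULL) {
  period <- match.arg(period)
  stopifnot(min_grains >= 1L)
  records <- as_pollen_records(records)
  records <- records[records$period == period, , drop = FALSE]
  if (nrow(records) == 0L) {
    stop(sprintf("no pollen records for period '%s'", period), call. = FALSE)
  }
  agg <- stats::aggregate(grains ~ specimen_id + pollinator + plant,
                          data = records, FUN = sum)
  agg <- agg[agg$grains >= min_grains, , drop = FALSE]
  if (nrow(agg) == 0L) {
    stop(sprintf("no pollen load reaches the %d-grain threshold", min_grains),
         call. = FALSE)
  }
  links <- unique(agg[, c("plant", "pollinator")])
  links$layer <- if (period == "diurnal") "P_d" else "P_n"
  if (is.null(name)) name <- links$layer[1L]
  new_bipartite_matrix(links, name)
}

#' Superimpose bipartite matrices
#'
#' Union of species sets and link sets across two or more matrices, each
#' union link keeping the union of its provenance tags. The resulting link
#' set is order-independent; order only decides bookkeeping order of tags.
#'
#' @param matrices list of `bipartite_matrix` objects (length >= 2).
#' @param name id of the union matrix.
#' @return A `bipartite_matrix`.
#' @export
superimpose <- function(matrices, name) {
  stopifnot(is.list(matrices), length(matrices) >= 2L,
            all(vapply(matrices, inherits, logical(1), "bipartite_matrix")))
  links <- do.call(rbind, lapply(matrices, function(M) {
    idx <- which(M$cells == 1L, arr.ind = TRUE)
    do.call(rbind, lapply(names(M$layers), function(ly) {
      keep <- M$layers[[ly]][idx]
      data.frame(plant = M$plants[idx[keep, 1L]],
                 pollinator = M$pollinators[idx[keep, 2L]],
                 layer = ly, stringsAsFactors = FALSE)
    }))
  }))
  links <- unique(links)
  new_bipartite_matrix(links, name)
}

#' Tally links by detection-source overlap
#'
#' Assigns every link of a (typically superimposed) matrix to exactly one of
#' seven disjoint provenance categories: detected only by diurnal visitation
#' (`V_d`), only by diurnal pollen (`P_d`), only by nocturnal pollen
#' (`P_n`), by each pairwise combination, or by all three methods.
#'
#' @param M a `bipartite_matrix` with populated provenance layers.
#' @return Object of class `overlap_tally`: named integer vector over the 7
#'   categories with attribute `total` (= union link count).
#' @export
overlap_tally <- function(M) {
  stopifnot(inherits(M, "bipartite_matrix"))
  idx <- which(M$cells == 1L, arr.ind = TRUE)
  tags <- matrix(FALSE, nrow(idx), 3L, dimnames = list(NULL, LAYER_NAMES))
  for (ly in names(M$layers)) tags[, ly] <- M$layers[[ly]][idx]
  if (any(rowSums(tags) == 0L)) {
    stop("internal consistency error: link with empty provenance",
         call. = FALSE)
  }
  key <- paste0(ifelse(tags[, "V_d"], "V_d", ""),
                ifelse(tags[, "P_d"], "+P_d", ""),
                ifelse(tags[, "P_n"], "+P_n", ""))
  key <- sub("^\\+", "", key)
  cats <- c("V_d", "P_d", "P_n", "V_d+P_d", "V_d+P_n", "P_d+P_n",
            "V_d+P_d+P_n")
  counts <- vapply(cats, function(k) sum(key == k), integer(1))
  stopifnot(sum(counts) == nrow(idx))
  structure(counts, total = nrow(idx), class = "overlap_tally")
}

#' @export
print.overlap_tally <- function(x, ...) {
  cat("link provenance tally (", attr(x, "total"), " links):\n", sep = "")
  print(unclass(x)[seq_along(x)])
  invisible(x)
}

#' Write a bipartite matrix to CSV with a JSON provenance sidecar
#'
#' The CSV has plant labels in the first column, pollinator labels as the
#' header, and 0/1 cells. The sidecar (`<path>.json`) stores the matrix name
#' and per-link provenance tags.
#'
#' @param M a `bipartite_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bipartite_matrix <- function(M, path) {
  stopifnot(inherits(M, "bipartite_matrix"))
  df <- data.frame(plant = M$plants, M$cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- as.data.frame(M)
  jsonlite::write_json(
    list(name = M$name, links = side),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a bipartite matrix written by [write_bipartite_matrix()]
#'
#' @param path CSV path; the `<path>.json` sidecar is read when present,
#'   otherwise all links are tagged with `default_layer`.
#' @param default_layer provenance tag for sidecar-less files.
#' @return A `bipartite_matrix`.
#' @export
read_bipartite_matrix <- function(path, default_layer = "V_d") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    links <- meta$links
    rows <- lapply(seq_len(nrow(links)), function(i) {
      tags <- strsplit(links$provenance[i], "+", fixed = TRUE)[[1L]]
      data.frame(plant = links$plant[i], pollinator = links$pollinator[i],
                 layer = tags, stringsAsFactors = FALSE)
    })
    return(new_bipartite_matrix(do.call(rbind, rows), meta$name))
  }
  cells <- as.matrix(df[, -1L, drop = FALSE])
  idx <- which(cells == 1, arr.ind = TRUE)
  links <- data.frame(plant = df[[1L]][idx[, 1L]],
                      pollinator = colnames(cells)[idx[, 2L]],
                      layer = default_layer, stringsAsFactors = FALSE)
  new_bipartite_matrix(links, sub("\\.csv$", "", basename(path)))
}
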