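# Containers and file I/O for landmark configurations, bilateral counts and
# categorical trait states.

#' Landmark configuration
#'
#' A single digitization of one specimen: an `L x D` matrix of Cartesian
#' landmark coordinates (`D` = 2 or 3) with landmark labels, a specimen
#' identifier and a replicate number. All configurations entering one analysis
#' must share `L`, `D` and the landmark order.
#'
#' @param coords Numeric `L x D` matrix (`L >= 3`, `D` 2 or 3), all finite.
#' @param specimen_id Character scalar identifying the specimen.
#' @param replicate Integer replicate (digitization session) number, `>= 1`.
#' @param landmark_names Optional character vector of `L` landmark labels;
#'   defaults to rownames of `coords` or `"lm1"..."lmL"`.
#' @return An object of class `"landmark_config"`.
#' @examples
#' cfg <- landmark_config(cbind(c(-1, 1, 0), c(0, 0, 1)), "spec1")
#' cfg
#' @export
landmark_config <- function(coords, specimen_id, replicate = 1L,
                            landmark_names = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) < 3L)
    stop("a landmark configuration needs at least 3 landmarks, got ",
         nrow(coords))
  if (!ncol(coords) %in% c(2L, 3L))
    stop("coordinate dimension must be 2 or 3, got ", ncol(coords))
  if (!all(is.finite(coords)))
    stop("non-finite coordinate in specimen '", specimen_id,
         "': missing landmarks are not supported, exclude the specimen")
  if (is.null(landmark_names)) landmark_names <- rownames(coords)
  if (is.null(landmark_names))
    landmark_names <- paste0("lm", seq_len(nrow(coords)))
  if (length(landmark_names) != nrow(coords))
    stop("landmark_names length does not match number of landmarks")
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L)
    stop("replicate must be an integer >= 1")
  dimnames(coords) <- list(landmark_names,
                           c("x", "y", "z")[seq_len(ncol(coords))])
  structure(list(coords = coords,
                 specimen_id = as.character(specimen_id),
                 replicate = replicate,
                 landmark_names = as.character(landmark_names)),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration: specimen '", x$specimen_id,
      "', replicate ", x$replicate, "\n", sep = "")
  cat("  ", nrow(x$coords), " landmarks in ", ncol(x$coords), "D\n", sep = "")
  invisible(x)
}

#' Declare the bilateral symmetry of a landmark set
#'
#' Records which landmarks form left/right pairs and which lie on the midline
#' (median landmarks). Indices are 1-based positions in the landmark order of
#' the configurations the map will be used with.
#'
#' @param pairs Two-column matrix (or list of length-2 vectors) of
#'   (left, right) landmark indices.
#' @param medians Integer vector of median (midline) landmark indices.
#' @return An object of class `"symmetry_map"` with components `pairs`
#'   (k x 2 integer matrix) and `medians`.
#' @seealso [validate_symmetry_map()]
#' @examples
#' symmetry_map(pairs = rbind(c(1, 2), c(4, 5)), medians = c(3, 6))
#' @export
symmetry_map <- function(pairs, medians = integer()) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("left", "right")))
  medians <- as.integer(medians)
  if (anyNA(pairs) || anyNA(medians))
    stop("symmetry map indices must be integers")
  structure(list(pairs = pairs, medians = medians), class = "symmetry_map")
}

#' @export
print.symmetry_map <- function(x, ...) {
  cat("Symmetry map:", nrow(x$pairs), "landmark pairs,",
      length(x$medians), "median landmarks\n")
  invisible(x)
}

#' Validate a symmetry map against a landmark count
#'
#' Checks that all indices are in `1..L`, used at most once, and that paired
#' and median sets are disjoint. Object symmetry is undefined without at least
#' one landmark pair.
#'
#' @param map A [symmetry_map()].
#' @param L Number of landmarks in the configurations the map describes.
#' @return The map, invisibly augmented with attributes `k` (number of pairs)
#'   and `u` (number of medians).
#' @export
validate_symmetry_map <- function(map, L) {
  stopifnot(inherits(map, "symmetry_map"))
  L <- as.integer(L)
  if (nrow(map$pairs) == 0L)
    stop("symmetry map has no landmark pairs; object symmetry requires ",
         "at least one pair")
  idx <- c(t(map$pairs), map$medians)
  bad <- idx[idx < 1L | idx > L]
  if (length(bad))
    stop("symmetry map index out of range (L = ", L, "): ",
         paste(unique(bad), collapse = ", "))
  dup <- idx[duplicated(idx)]
  if (length(dup))
    stop("symmetry map index used more than once: ",
         paste(unique(dup), collapse = ", "))
  attr(map, "k") <- nrow(map$pairs)
  attr(map, "u") <- length(map$medians)
  map
}

#' Bundle replicated landmark configurations into a study sample
#'
#' A study sample holds every digitization of one population: `n` specimens
#' each digitized `r` times (`r` replicates quantify measurement error in the
#' Procrustes ANOVA). All configurations must be dimensionally congruent and
#' replication must be balanced.
#'
#' @param configs List of [landmark_config()] objects.
#' @param population Population label (e.g. `"Erwitte"`).
#' @param replicates Expected replicate count `r`; inferred when `NULL`.
#' @return An object of class `"study_sample"`.
#' @export
study_sample <- function(configs, population = "sample", replicates = NULL) {
  if (!length(configs) || !all(vapply(configs, inherits, TRUE,
                                      "landmark_config")))
    stop("configs must be a non-empty list of landmark_config objects")
  L <- nrow(configs[[1L]]$coords)
  D <- ncol(configs[[1L]]$coords)
  nms <- configs[[1L]]$landmark_names
  for (cf in configs) {
    if (nrow(cf$coords) != L || ncol(cf$coords) != D)
      stop("configurations are not congruent: specimen '", cf$specimen_id,
           "' has ", nrow(cf$coords), " landmarks in ", ncol(cf$coords),
           "D, expected ", L, " in ", D, "D")
    if (!identical(cf$landmark_names, nms))
      stop("landmark name order differs in specimen '", cf$specimen_id, "'")
  }
  ids <- vapply(configs, `[[`, "", "specimen_id")
  reps <- vapply(configs, `[[`, 1L, "replicate")
  if (anyDuplicated(paste(ids, reps, sep = "\r")))
    stop("duplicate (specimen, replicate) combination in sample")
  tab <- table(ids)
  r <- unname(tab[1L])
  if (length(unique(as.integer(tab))) != 1L)
    stop("unbalanced replication: specimens have differing replicate ",
         "counts (", paste(names(tab), as.integer(tab), sep = "=",
                           collapse = ", "), ")")
  if (!is.null(replicates) && r != as.integer(replicates))
    stop("sample has r = ", r, " replicates per specimen, expected ",
         replicates)
  ord <- order(match(ids, unique(ids)), reps)
  configs <- configs[ord]
  structure(list(configs = configs,
                 population = as.character(population),
                 specimen_ids = unique(ids),
                 n = length(unique(ids)),
                 r = as.integer(r),
                 L = L, D = D,
                 landmark_names = nms),
            class = "study_sample")
}

#' @export
print.study_sample <- function(x, ...) {
  cat("Study sample '", x$population, "': ", x$n, " specimens x ", x$r,
      " replicates, ", x$L, " landmarks in ", x$D, "D\n", sep = "")
  invisible(x)
}

# L x D x N array of raw coordinates, with an index data.frame
sample_array <- function(sample) {
  arr <- array(unlist(lapply(sample$configs, `[[`, "coords"), use.names = FALSE),
               dim = c(sample$L, sample$D, length(sample$configs)))
  idx <- data.frame(
    specimen = vapply(sample$configs, `[[`, "", "specimen_id"),
    replicate = vapply(sample$configs, `[[`, 1L, "replicate"),
    stringsAsFactors = FALSE)
  list(coords = arr, index = idx)
}

#' Read a MeshLab PickPoints landmark file
#'
#' Parses the XML `.pp` files MeshLab writes when landmarks are picked on a
#' 3D model. Points are returned in file order. A point flagged inactive
#' (`active="0"`) is an error rather than silently dropped: clean the file in
#' MeshLab first so that the landmark order is unambiguous.
#'
#' @param path Path to a `.pp` file.
#' @param specimen_id Specimen identifier; defaults to the file name without
#'   extension. Replicate identity is not stored in `.pp` files (MeshLab
#'   writes one file per picking session) and must be supplied.
#' @param replicate Replicate number for this digitization session.
#' @return A [landmark_config()] with the points in file order.
#' @export
read_pickpoints <- function(path, specimen_id = NULL, replicate = 1L) {
  if (is.null(specimen_id))
    specimen_id <- sub("\\.[^.]*$", "", basename(path))
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("malformed PickPoints XML in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  pts <- xml2::xml_find_all(doc, ".//point")
  if (!length(pts))
    stop("no <point> elements found in '", path, "'")
  get_attr <- function(nodes, a) xml2::xml_attr(nodes, a)
  active <- get_attr(pts, "active")
  if (any(!is.na(active) & active %in% c("0", "false")))
    stop("inactive point(s) present in '", path, "' (positions ",
         paste(which(!is.na(active) & active %in% c("0", "false")),
               collapse = ", "),
         "); remove or reactivate them in MeshLab before import")
  coords <- sapply(c("x", "y", "z"), function(a) {
    v <- get_attr(pts, a)
    if (anyNA(v))
      stop("point ", which(is.na(v))[1L], " in '", path,
           "' is missing its '", a, "' attribute")
    as.numeric(v)
  })
  coords <- matrix(coords, ncol = 3L)
  nms <- get_attr(pts, "name")
  if (anyNA(nms)) nms <- NULL
  landmark_config(coords, specimen_id, replicate, landmark_names = nms)
}

#' Read landmark configurations from a CSV or TPS table
#'
#' The CSV dialect is long format with columns `specimen_id`, `replicate`,
#' `landmark`, `x`, `y` and optionally `z`. The TPS dialect is the standard
#' `LM=` / `ID=` block format; a replicate number may be encoded in the ID as
#' a `"__rep<k>"` suffix (otherwise replicate 1 is assumed).
#'
#' @param path File path.
#' @param dialect `"csv"` or `"tps"`.
#' @return A list of [landmark_config()] objects grouped by
#'   (specimen, replicate), congruence-checked.
#' @export
read_landmark_table <- function(path, dialect = c("csv", "tps")) {
  dialect <- match.arg(dialect)
  configs <- if (dialect == "csv") read_landmark_csv(path)
             else read_landmark_tps(path)
  check_congruence(configs, path)
  configs
}

read_landmark_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "replicate", "landmark", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("landmark CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  has_z <- "z" %in% names(df)
  key <- paste(df$specimen_id, df$replicate, sep = "\r")
  lapply(unique(key), function(k) {
    block <- df[key == k, , drop = FALSE]
    coords <- cbind(x = block$x, y = block$y)
    if (has_z) coords <- cbind(coords, z = block$z)
    landmark_config(coords, block$specimen_id[1L],
                    as.integer(block$replicate[1L]),
                    landmark_names = as.character(block$landmark))
  })
}

read_landmark_tps <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lm_at <- grep("^LM3?=", lines)
  if (!length(lm_at)) stop("no LM= records found in TPS file '", path, "'")
  lapply(seq_along(lm_at), function(b) {
    i <- lm_at[b]
    L <- as.integer(sub("^LM3?=", "", lines[i]))
    is3d <- startsWith(lines[i], "LM3")
    coord_lines <- lines[(i + 1L):(i + L)]
    coords <- do.call(rbind, lapply(strsplit(coord_lines, "[ \t,]+"),
                                    as.numeric))
    if (ncol(coords) != (if (is3d) 3L else 2L))
      stop("TPS block ", b, " in '", path, "': expected ",
           if (is3d) 3L else 2L, " coordinates per line")
    block_end <- if (b < length(lm_at)) lm_at[b + 1L] - 1L else length(lines)
    id_line <- grep("^ID=", lines[(i + L + 1L):block_end], value = TRUE)
    id <- if (length(id_line)) sub("^ID=", "", id_line[1L])
          else paste0("specimen", b)
    rep_k <- 1L
    if (grepl("__rep[0-9]+$", id)) {
      rep_k <- as.integer(sub(".*__rep", "", id))
      id <- sub("__rep[0-9]+$", "", id)
    }
    landmark_config(coords, id, rep_k)
  })
}

check_congruence <- function(configs, path) {
  Ls <- vapply(configs, function(cf) nrow(cf$coords), 1L)
  Ds <- vapply(configs, function(cf) ncol(cf$coords), 1L)
  if (length(unique(Ls)) > 1L || length(unique(Ds)) > 1L) {
    mode_L <- as.integer(names(sort(table(Ls), decreasing = TRUE))[1L])
    off <- vapply(configs, `[[`, "", "specimen_id")[Ls != mode_L | Ds != Ds[1L]]
    stop("incongruent landmark counts in '", path, "': offending specimens ",
         paste(unique(off), collapse = ", "))
  }
  invisible(configs)
}

#' Write landmark configurations as a long-format CSV
#'
#' Coordinates are written at full double precision so that a write/read
#' round trip is exact.
#'
#' @param sample A [study_sample()] or list of [landmark_config()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(sample, path) {
  configs <- if (inherits(sample, "study_sample")) sample$configs else sample
  rows <- lapply(configs, function(cf) {
    d <- data.frame(specimen_id = cf$specimen_id,
                    replicate = cf$replicate,
                    landmark = cf$landmark_names,
                    x = sprintf("%.17g", cf$coords[, 1L]),
                    y = sprintf("%.17g", cf$coords[, 2L]),
                    stringsAsFactors = FALSE)
    if (ncol(cf$coords) == 3L) d$z <- sprintf("%.17g", cf$coords[, 3L])
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read bilateral count records
#'
#' Expects columns `specimen_id`, `population`, `trait`, `right_count`,
#' `left_count`, `size` (the test-length covariate, in mm).
#'
#' @param path CSV path.
#' @return A validated data frame of class `"meristic_records"`.
#' @export
read_counts <- function(path) {
  meristic_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a data frame of bilateral counts
#'
#' @param df Data frame with columns `specimen_id`, `population`, `trait`,
#'   `right_count`, `left_count`, `size`.
#' @return `df` with class `"meristic_records"` prepended.
#' @export
meristic_records <- function(df) {
  need <- c("specimen_id", "population", "trait", "right_count",
            "left_count", "size")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("count table is missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("right_count", "left_count")) {
    v <- df[[col]]
    if (anyNA(v) || any(v < 0) || any(v != round(v)))
      stop(col, " must be non-negative integers")
  }
  if (anyNA(df$size) || any(df$size <= 0))
    stop("size (test length) must be positive")
  class(df) <- unique(c("meristic_records", class(df)))
  df
}

#' Built-in categorical trait vocabularies
#'
#' Ordered state vocabularies for the scored categorical characters: the
#' development of the subanal fasciole and the projection of the labrum over
#' the peristome.
#'
#' @return Named list of ordered state vectors.
#' @export
trait_vocabularies <- function() {
  list(
    fasciole = c("absent", "incomplete", "protofasciole", "parafasciole",
                 "orthofasciole"),
    labrum = c("open", "covered", "exceeding"))
}

#' Read categorical trait state records
#'
#' Expects columns `specimen_id`, `population`, `trait`, `state`. States are
#' validated against `vocab` (per-trait ordered vocabularies; traits absent
#' from `vocab` accept any state, ordered by first appearance).
#'
#' @param path CSV path.
#' @param vocab Named list of state vocabularies, as [trait_vocabularies()].
#' @return Data frame of validated records.
#' @export
read_states <- function(path, vocab = trait_vocabularies()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "population", "trait", "state")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("state table is missing column(s): ", paste(miss, collapse = ", "))
  for (tr in intersect(unique(df$trait), names(vocab))) {
    bad <- setdiff(df$state[df$trait == tr], vocab[[tr]])
    if (length(bad))
      stop("unknown state(s) for trait '", tr, "': ",
           paste(unique(bad), collapse = ", "))
  }
  df
}
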