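#' Electrode montages
#'
#' A montage describes the electrode layout the pipeline assumes: ordered
#' electrode names, 2-D scalp coordinates (unit-disc top view, x towards the
#' right ear, y towards the nasion), a scalp-region label per electrode
#' (frontal, central, temporal, parietal, occipital) and a symmetric
#' nearest-neighbour adjacency used by the Hjorth surface Laplacian.
#'
#' `standard_montage()` returns the 32-electrode 10/20 montage used
#' throughout: Fp1, Fp2, F7, F3, Fz, F4, F8, FC5, FC1, FC2, FC6, A1, T7, T8,
#' A2, C3, Cz, C4, CP5, CP1, CP2, CP6, P7, P3, Pz, P4, P8, PO3, PO4, O1, Oz,
#' O2. Region membership follows standard 10/20 nomenclature prefixes, with
#' the ear electrodes A1/A2 grouped temporal by proximity. Both the electrode
#' table and the adjacency are shipped as plain-text files under
#' `inst/extdata/` and can be replaced via [read_montage()].
#'
#' @param electrode_file,adjacency_file Paths to tab-separated tables. The
#'   electrode table needs columns `name`, `x`, `y`, `region`; the adjacency
#'   table columns `from`, `to` (one undirected neighbour pair per row, in
#'   either order; the relation is symmetrized on read).
#' @return An object of class `eeg_montage`: a list with `names` (character),
#'   `positions` (n x 2 matrix), `region` (named character), `neighbors`
#'   (named list of character vectors) and `n_channels`.
#' @examples
#' m <- standard_montage()
#' m$n_channels
#' m$neighbors[["Cz"]]
#' @export
standard_montage <- function() {
  read_montage(
    system.file("extdata", "montage_10_20_32.tsv", package = "eegfp"),
    system.file("extdata", "adjacency_10_20_32.tsv", package = "eegfp")
  )
}

#' @rdname standard_montage
#' @export
read_montage <- function(electrode_file, adjacency_file) {
  tab <- utils::read.delim(electrode_file, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "x", "y", "region") %in% names(tab)))
  if (anyDuplicated(tab$name)) stop("duplicate electrode names in montage")
  adj <- utils::read.delim(adjacency_file, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to") %in% names(adj)))
  unknown <- setdiff(unique(c(adj$from, adj$to)), tab$name)
  if (length(unknown) > 0) {
    stop("adjacency refers to electrodes not in the montage: ",
         paste(unknown, collapse = ", "))
  }
  nb <- lapply(tab$name, function(e) {
    sort(unique(c(adj$to[adj$from == e], adj$from[adj$to == e])))
  })
  names(nb) <- tab$name
  deg <- lengths(nb)
  if (any(deg < 2)) {
    stop("every electrode needs >= 2 neighbors; offending: ",
         paste(tab$name[deg < 2], collapse = ", "))
  }
  pos <- cbind(x = tab$x, y = tab$y)
  rownames(pos) <- tab$name
  region <- tab$region
  names(region) <- tab$name
  structure(
    list(names = tab$name, positions = pos, region = region,
         neighbors = nb, n_channels = nrow(tab)),
    class = "eeg_montage"
  )
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", x$n_channels, " electrodes; regions: ",
      paste(sprintf("%s=%d", names(table(x$region)), table(x$region)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Scalp region labels in anterior-to-posterior order
#' @return Character vector of the five region labels.
#' @export
scalp_regions <- function() {
  c("frontal", "central", "temporal", "parietal", "occipital")
}

# indices of electrodes in a given region, in montage order
region_indices <- function(montage, region) {
  which(montage$region[montage$names] == region)
}
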