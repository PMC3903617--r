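# Rotamer library: coarse backbone-independent chi-angle priors used for
# side-chain building and ensemble sampling.

#' Load a rotamer library
#'
#' Whitespace-delimited text with columns
#' `residue chi1 chi2 chi3 chi4 prob`; chi angles in degrees, NA for
#' absent angles; probabilities sum to 1 within each residue type.
#'
#' @param path file path; default is the bundled coarse library.
#' @return data frame of class `rotamer_library`, sorted by decreasing
#'   probability within residue.
#' @export
load_rotamer_library <- function(path = system.file("extdata", "rotamer_library.tsv",
                                                    package = "abmature")) {
  if (!file.exists(path)) stop("rotamer library not found: ", path)
  rl <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("residue", "chi1", "chi2", "chi3", "chi4", "prob")
  if (!all(need %in% names(rl)))
    stop("rotamer library must have columns: ", paste(need, collapse = ", "))
  for (res in unique(rl$residue)) {
    p <- rl$prob[rl$residue == res]
    if (abs(sum(p) - 1) > 1e-6)
      stop("rotamer probabilities for ", res, " sum to ", sum(p))
    nchi_lib <- sum(!is.na(unlist(rl[rl$residue == res, ][1, c("chi1", "chi2", "chi3", "chi4")])))
    nchi_topo <- sidechain_topology[[res]]$nchi
    if (!is.null(nchi_topo) && nchi_lib != nchi_topo)
      stop(sprintf("rotamer chi count for %s (%d) does not match topology (%d)",
                   res, nchi_lib, nchi_topo))
  }
  rl <- rl[order(rl$residue, -rl$prob), ]
  rownames(rl) <- NULL
  class(rl) <- c("rotamer_library", "data.frame")
  rl
}

default_rot_cache <- new.env(parent = emptyenv())

default_rotamer_library <- function() {
  if (is.null(default_rot_cache$rl)) default_rot_cache$rl <- load_rotamer_library()
  default_rot_cache$rl
}

# chi vector of a library row
rot_chis <- function(row, nchi) {
  if (nchi == 0) return(numeric(0))
  as.numeric(row[1, paste0("chi", seq_len(nchi))])
}

#' Pick a rotamer for a residue type
#'
#' @param res 3-letter residue name.
#' @param policy `"most_probable"`, an integer k (k-th most probable), or
#'   `"sample"` (draw from the prior; uses the current RNG stream).
#' @param library a rotamer library.
#' @return numeric vector of chi angles (degrees); length 0 for Ala/Gly.
#' @export
pick_rotamer <- function(res, policy = "most_probable",
                         library = default_rotamer_library()) {
  rows <- library[library$residue == res, , drop = FALSE]
  if (nrow(rows) == 0) stop("no rotamers for residue ", res)
  nchi <- sidechain_topology[[res]]$nchi
  if (is.numeric(policy)) {
    k <- as.integer(policy)
    if (k < 1 || k > nrow(rows)) stop("rotamer index ", k, " out of range for ", res)
    return(rot_chis(rows[k, , drop = FALSE], nchi))
  }
  if (identical(policy, "most_probable"))
    return(rot_chis(rows[1, , drop = FALSE], nchi))
  if (identical(policy, "sample")) {
    k <- sample.int(nrow(rows), 1, prob = rows$prob)
    return(rot_chis(rows[k, , drop = FALSE], nchi))
  }
  stop("unknown rotamer policy: ", policy)
}
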