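#' Clinical code-grouping constants
#'
#' Diagnosis codes are grouped into 283 CCS-style categories, procedure codes
#' into 231 CCS-style categories, and drug codes into 893 pharmacy classes.
#' These cardinalities are fixed properties of the feature layout used
#' throughout the package.
#'
#' @format Named integer vector with elements `dx`, `proc`, `drug`.
#' @export
CODE_GROUP_SIZES <- c(dx = 283L, proc = 231L, drug = 893L)

#' Build synthetic raw-code to group maps
#'
#' Constructs surjective maps from raw diagnosis / procedure / drug code
#' tokens onto the fixed group vocabularies (283 / 231 / 893 groups). Every
#' raw code maps to exactly one group and every group receives at least one
#' raw code, so the grouped feature blocks are fully reachable. Real
#' crosswalks (CCS, NDC pharmacy classes) can be substituted by supplying any
#' object with the same shape.
#'
#' @param n_dx_codes,n_proc_codes,n_drug_codes Number of distinct raw codes
#'   per code system; each must be at least the corresponding group count.
#' @param seed Integer seed; the maps are deterministic given the seed.
#' @return An object of class `code_group_maps`: a list with named integer
#'   vectors `dx_map`, `proc_map`, `drug_map` (names are raw code tokens,
#'   values are group ids).
#' @export
build_code_group_maps <- function(n_dx_codes, n_proc_codes, n_drug_codes,
                                  seed = 1L) {
  counts <- c(dx = n_dx_codes, proc = n_proc_codes, drug = n_drug_codes)
  for (sys in names(counts)) {
    if (counts[[sys]] < CODE_GROUP_SIZES[[sys]]) {
      stop(sprintf(
        "%s: %d raw codes cannot cover %d groups",
        sys, counts[[sys]], CODE_GROUP_SIZES[[sys]]
      ), call. = FALSE)
    }
  }
  prefixes <- c(dx = "DX", proc = "PR", drug = "ND")
  maps <- with_seed(seed, {
    lapply(names(counts), function(sys) {
      n <- as.integer(counts[[sys]])
      g <- CODE_GROUP_SIZES[[sys]]
      # one anchor code per group guarantees surjectivity; the rest uniform
      groups <- c(sample.int(g), sample.int(g, n - g, replace = TRUE))
      groups <- groups[sample.int(n)]
      names(groups) <- sprintf("%s%06d", prefixes[[sys]], seq_len(n))
      groups
    })
  })
  names(maps) <- paste0(names(counts), "_map")
  structure(maps, class = "code_group_maps")
}

#' @export
print.code_group_maps <- function(x, ...) {
  cat("<code_group_maps>\n")
  for (nm in names(x)) {
    cat(sprintf(
      "  %s: %d raw codes -> %d groups\n",
      nm, length(x[[nm]]), length(unique(x[[nm]]))
    ))
  }
  invisible(x)
}

# group -> raw-code lookup used by the generator: codes ordered by group id
# plus start offsets, for O(1) vectorized sampling within groups.
group_code_index <- function(map, n_groups) {
  ord <- order(map)
  codes <- names(map)[ord]
  grp <- map[ord]
  sizes <- tabulate(grp, nbins = n_groups)
  starts <- cumsum(c(1L, sizes[-n_groups]))
  list(codes = codes, starts = starts, sizes = sizes)
}
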