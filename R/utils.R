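#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join lag n
#' @importFrom purrr map map_dbl map2 pmap imap
#' @importFrom stats median dist hclust cutree quantile rnbinom rnorm runif
#'   cophenetic
NULL

# Validate a length-3 positive numeric spacing vector (um per axis).
check_spacing <- function(spacing) {
  if (!is.numeric(spacing) || length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    abort("`spacing` must be three positive, finite values (um per axis).")
  }
  as.numeric(spacing)
}

# Physical coordinates (um) of voxel centers along one axis: voxel i (1-based)
# sits at (i - 1) * spacing, so the first voxel center defines the origin and
# z grows away from the imaging face.
axis_coords <- function(n, spacing) (seq_len(n) - 1) * spacing

vec_norm <- function(v) sqrt(sum(v^2))

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# md5 of an object's canonical JSON; used to stamp pipeline outputs so a
# config change is visible in every file it produced.
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(f))
}
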