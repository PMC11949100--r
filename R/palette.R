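#' Anterior-segment class codes
#'
#' The fixed label vocabulary used by every mask in the package:
#' `0 = background`, `1 = pterygium`, `2 = pupil`, `3 = cornea`.
#'
#' @return Named integer vector mapping class name to code.
#' @export
#' @examples
#' ptery_classes()
ptery_classes <- function() {
  c(background = 0L, pterygium = 1L, pupil = 2L, cornea = 3L)
}

#' Display palette for anterior-segment classes
#'
#' RGB display colours (0-255) for each class code.  The palette is
#' bijective, so an RGB-encoded mask in these colours can be decoded back
#' to class codes exactly.
#'
#' @return Integer matrix with one row per class (rownames = class names,
#'   in code order 0..3) and columns `r`, `g`, `b`.
#' @export
ptery_palette <- function() {
  pal <- rbind(
    background = c(0L,   0L,   0L),
    pterygium  = c(214L, 77L,  64L),
    pupil      = c(38L,  38L,  153L),
    cornea     = c(120L, 190L, 216L)
  )
  colnames(pal) <- c("r", "g", "b")
  pal
}

#' Resolve a class name or code to an integer code
#'
#' @param class Class name (`"cornea"`, `"pupil"`, `"pterygium"`,
#'   `"background"`) or an integer code in 0..3.
#' @return Integer class code.
#' @export
class_code <- function(class) {
  codes <- ptery_classes()
  if (is.character(class)) {
    class <- match.arg(class, names(codes))
    return(unname(codes[class]))
  }
  cls <- as.integer(class)
  if (length(cls) != 1L || is.na(cls) || !cls %in% codes)
    stop("unknown class: ", deparse(class), call. = FALSE)
  cls
}

# validate that a matrix only carries known class codes
validate_mask <- function(mask, where = "mask") {
  if (!is.matrix(mask)) stop(where, " must be a matrix", call. = FALSE)
  bad <- setdiff(unique(as.vector(mask)), ptery_classes())
  if (length(bad)) {
    counts <- table(mask[mask %in% bad])
    stop(where, " contains unknown class codes: ",
         paste0(names(counts), " (n=", as.integer(counts), ")",
                collapse = ", "),
         call. = FALSE)
  }
  storage.mode(mask) <- "integer"
  mask
}
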