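#' Spatial-domain image enhancement
#'
#' Enhancement is modelled as an operator applied directly to the pixel grid:
#' `g = EH(f)`. The operator itself is a choice, so three concrete dialects
#' are offered:
#' \describe{
#'   \item{`stretch`}{linear contrast stretch mapping the channel minimum to 0
#'     and maximum to 1 (the default);}
#'   \item{`hist_eq`}{cumulative-histogram equalization per channel — each
#'     pixel is mapped to its empirical CDF value, so a level holding the
#'     lowest q fraction of pixels maps to q;}
#'   \item{`identity`}{returns the input unchanged.}
#' }
#' All methods preserve the intensity ordering of pixels within a channel. A
#' constant channel has zero dynamic range; `stretch` returns it unchanged
#' with a warning.
#'
#' @param image numeric matrix or `H x W x 3` array in `[0, 1]`.
#' @param method one of `"stretch"`, `"hist_eq"`, `"identity"`.
#' @return enhanced image of the same shape, values in `[0, 1]`.
#' @examples
#' img <- matrix(seq(0.2, 0.7, length.out = 16), 4, 4)
#' range(enhance(img, "stretch"))
#' @export
enhance <- function(image, method = c("stretch", "hist_eq", "identity")) {
  image <- as_image(image)
  method <- match.arg(method)
  if (method == "identity") return(image)
  per_channel <- function(ch) {
    if (method == "stretch") {
      rng <- range(ch)
      if (diff(rng) == 0) {
        warn("constant channel: zero dynamic range, returned unchanged")
        return(ch)
      }
      (ch - rng[1]) / diff(rng)
    } else {
      cdf <- ecdf(as.vector(ch))
      matrix(cdf(as.vector(ch)), nrow(ch), ncol(ch))
    }
  }
  if (is_rgb(image)) {
    out <- image
    for (k in 1:3) out[, , k] <- per_channel(image[, , k])
    out
  } else {
    per_channel(image)
  }
}
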