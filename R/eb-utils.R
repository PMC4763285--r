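# thin wrappers around EBImage primitives: accept and return plain numeric
# matrices (EBImage's S4 dispatch needs Image objects)

eb_gblur <- function(m, sigma, boundary = "replicate") {
  # gblur's kernel (radius 2*ceiling(3*sigma)+1) must fit inside the image
  smax <- (min(dim(m)) - 3) / 7
  if (smax <= 0) return(matrix(mean(m), nrow(m), ncol(m)))
  sigma <- min(sigma, smax)
  EBImage::imageData(
    EBImage::gblur(EBImage::Image(m), sigma = sigma, boundary = boundary)
  )
}

eb_filter2 <- function(m, kernel, boundary = "replicate") {
  EBImage::imageData(
    EBImage::filter2(EBImage::Image(m), kernel, boundary = boundary)
  )
}

eb_closing <- function(mask, brush) {
  EBImage::imageData(EBImage::closing(EBImage::Image(mask * 1), brush)) > 0.5
}

eb_fill_hull <- function(mask) {
  EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0.5
}

eb_bwlabel <- function(mask) {
  EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
}
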