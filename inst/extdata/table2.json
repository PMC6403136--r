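{
  "a": -2.6518,
  "b": 0.2231659,
  "c": -0.2045457,
  "d": -0.1530924,
  "A0": 38.9066,
  "se": {
    "a": 0.1174497,
    "b": 0.1174497,
    "c": 0.0269435,
    "d": 0.0354465
  },
  "meta": {
    "source": "published per-MII-oocyte euploidy model (nominal logistic fit, logit link)",
    "alpha": 0.05,
    "note": "Intercept is the testicular-NOA group at the centering age; b and c attach to the ejaculate-like group, d to the testicular-NOA group. The published equation header centers age at 38.9066 while the term rows print 37.9384; the header value is shipped."
  }
}
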