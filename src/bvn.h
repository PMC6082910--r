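#ifndef BIFACTORPRS_BVN_H
#define BIFACTORPRS_BVN_H

double bvn_cdf_scalar(double x, double y, double rho);
double bvn_pdf_scalar(double x, double y, double rho);
double bvn_rect_prob(double a1, double a2, double b1, double b2, double rho);
double bvn_rect_dprob(double a1, double a2, double b1, double b2, double rho);

#endif
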