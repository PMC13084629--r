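wavenumber_cm-1,eps_re,eps_im,kappa_re,kappa_im
800,2.10,0.00,0.0000e+00,0.0000e+00
900,2.12,0.02,1.0000e-06,2.0000e-06
1000,2.05,0.20,-3.0000e-06,8.0000e-06
1100,2.00,0.05,1.5000e-06,3.0000e-06
1200,2.08,0.01,5.0000e-07,5.0000e-07
1300,2.10,0.00,0.0000e+00,0.0000e+00
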