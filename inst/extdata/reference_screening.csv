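feature,r,p_printed,significant
RTST_DT1,-0.774,,TRUE
RTST_DT2,-0.705,,TRUE
RTST_DT3,-0.728,,TRUE
RTST_MEAN,-0.777,,TRUE
CNST_DT1,0.709,,TRUE
CNST_DT2,0.669,,TRUE
CNST_DT3,0.683,,TRUE
CNST_MEAN,0.718,,TRUE
NSC_DT1,0.524,,TRUE
NSC_DT2,0.528,,TRUE
NSC_DT3,0.343,,TRUE
NSC_MEAN,0.573,,TRUE
NUC_DT1,-0.337,,TRUE
NUC_DT2,-0.102,0.481,FALSE
NUC_DT3,-0.019,0.896,FALSE
NUC_MEAN,-0.215,0.135,FALSE
NA_DT1,0.165,0.254,FALSE
NA_DT2,0.387,,TRUE
NA_DT3,0.287,,TRUE
NA_MEAN,0.315,,TRUE
TTC_DT1,0.102,0.483,FALSE
TTC_DT2,-0.039,0.788,FALSE
TTC_DT3,-0.019,0.898,FALSE
TTC_MEAN,0.040,0.784,FALSE
TSC_DT1,-0.317,,TRUE
TSC_DT2,-0.355,,TRUE
TSC_DT3,0.009,0.954,FALSE
TSC_MEAN,-0.310,,TRUE
TSC_MAX_DT1,-0.190,0.187,FALSE
TSC_MAX_DT2,-0.240,0.093,FALSE
TSC_MAX_DT3,-0.025,0.863,FALSE
TSC_MAX_MEAN,-0.271,0.057,FALSE
TSC_MIN_DT1,-0.365,,TRUE
TSC_MIN_DT2,-0.365,,TRUE
TSC_MIN_DT3,0.063,0.663,FALSE
TSC_MIN_MEAN,-0.022,0.881,FALSE
HT_DT1,0.341,,TRUE
HT_DT2,0.455,,TRUE
HT_DT3,0.458,,TRUE
HT_MEAN,0.438,,TRUE
FN_DT1,-0.067,0.644,FALSE
FN_DT2,-0.248,0.083,FALSE
FN_DT3,-0.198,0.168,FALSE
FN_MEAN,-0.208,0.148,FALSE
SDX_DT1,0.159,0.269,FALSE
SDX_DT2,0.091,0.529,FALSE
SDX_DT3,0.122,0.398,FALSE
SDX_MEAN,0.131,0.364,FALSE
ETPX_DT1,0.155,0.282,FALSE
ETPX_DT2,-0.145,0.314,FALSE
ETPX_DT3,-0.163,0.257,FALSE
ETPX_MEAN,-0.072,0.622,FALSE
MVX_DT1,0.174,0.227,FALSE
MVX_DT2,0.264,0.064,FALSE
MVX_DT3,0.251,0.079,FALSE
MVX_MEAN,0.247,0.083,FALSE
MVY_DT1,0.321,,TRUE
MVY_DT2,0.461,,TRUE
MVY_DT3,0.314,,TRUE
MVY_MEAN,0.402,,TRUE
SDVX_DT1,0.114,0.431,FALSE
SDVX_DT2,0.165,0.252,FALSE
SDVX_DT3,0.025,0.866,FALSE
SDVX_MEAN,0.112,0.438,FALSE
SDVY_DT1,0.036,0.804,FALSE
SDVY_DT2,0.085,0.557,FALSE
SDVY_DT3,-0.044,0.763,FALSE
SDVY_MEAN,0.026,0.856,FALSE
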