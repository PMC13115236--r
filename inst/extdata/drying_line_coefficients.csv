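temperature_C,slope_per_s,intercept,mse
30,-1.46982169e-5,-0.59745164,0.30508460
40,-2.01117947e-5,-0.67151457,0.23127388
50,-2.48775171e-5,-0.44401679,0.26330223
60,-3.39803574e-5,-0.49186182,0.21446990
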