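249
250
251
252
253
254
255
256
257
259
261
265
266
267
269
270
273
304
305
306
307
339
340
400
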