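{"module":["v50","v1","v34","v42","v27","v21","v59","v31"],"targetsA":["v54","v43","v1","v32","v19"],"targetsB":["v42","v26","v54","v52","v31"],"diseaseX":["v16","v42","v32","v43","v51","v28","v33"],"diseaseY":["v55","v52","v12","v47","v32","v34"]}
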