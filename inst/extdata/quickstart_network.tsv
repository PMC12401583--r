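source	target	weight
v1	v16	1
v1	v21	1
v1	v44	1
v1	v48	1
v1	v50	1
v1	v55	1
v1	v59	1
v2	v4	1
v2	v19	1
v2	v25	1
v2	v35	1
v2	v46	1
v3	v5	1
v3	v6	1
v3	v9	1
v3	v32	1
v3	v39	1
v4	v7	1
v4	v15	1
v4	v25	1
v4	v59	1
v5	v19	1
v6	v9	1
v6	v12	1
v6	v35	1
v6	v56	1
v7	v23	1
v7	v47	1
v8	v19	1
v8	v38	1
v8	v40	1
v8	v52	1
v9	v32	1
v9	v39	1
v9	v47	1
v11	v14	1
v11	v15	1
v11	v24	1
v11	v32	1
v11	v49	1
v12	v15	1
v12	v37	1
v12	v48	1
v12	v53	1
v13	v60	1
v14	v18	1
v14	v21	1
v14	v47	1
v14	v57	1
v14	v58	1
v14	v60	1
v15	v36	1
v15	v38	1
v15	v44	1
v16	v17	1
v16	v19	1
v16	v20	1
v16	v60	1
v17	v30	1
v17	v41	1
v17	v57	1
v18	v21	1
v18	v40	1
v19	v25	1
v19	v26	1
v19	v30	1
v19	v31	1
v20	v40	1
v20	v60	1
v21	v25	1
v21	v37	1
v22	v34	1
v22	v45	1
v22	v53	1
v23	v30	1
v23	v36	1
v23	v56	1
v25	v39	1
v25	v42	1
v26	v35	1
v26	v48	1
v26	v55	1
v26	v56	1
v27	v31	1
v27	v37	1
v27	v42	1
v27	v43	1
v27	v56	1
v28	v31	1
v28	v38	1
v28	v40	1
v28	v41	1
v29	v40	1
v29	v52	1
v29	v54	1
v29	v57	1
v30	v37	1
v30	v42	1
v32	v38	1
v32	v44	1
v32	v49	1
v33	v38	1
v34	v42	1
v34	v50	1
v35	v47	1
v36	v43	1
v36	v60	1
v37	v44	1
v37	v45	1
v38	v47	1
v38	v49	1
v38	v55	1
v39	v44	1
v40	v44	1
v40	v51	1
v41	v52	1
v41	v56	1
v42	v52	1
v43	v54	1
v45	v50	1
v45	v55	1
v46	v52	1
v49	v58	1
v50	v59	1
v51	v55	1
v51	v56	1
v52	v58	1
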