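label,sweep,n_v,n_c,t2_ms,t3c_ms,t4c_ms,Tc_ms,t4g_ms,Tg_ms
Mesh 1,vertices,39042,1817,20.9,2.1,5.1,28.1,10.6,31.5
Mesh 2,vertices,81842,1817,20.9,4.0,5.2,30.1,10.6,31.5
Mesh 3,vertices,160052,1817,20.9,8.2,6.4,35.5,10.6,31.5
Mesh 4,vertices,256904,1817,20.9,13.1,5.7,39.7,10.6,31.5
Case 1,cubes,256904,576,8.6,13.0,5.3,26.9,5.3,13.9
Case 2,cubes,256904,929,11.6,13.1,5.4,30.1,7.8,19.4
Case 3,cubes,256904,1817,20.9,13.1,5.7,39.7,10.6,31.5
Case 4,cubes,256904,3715,39.9,13.3,5.3,58.5,18.9,58.8
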