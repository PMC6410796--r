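learner_id,item_id,t_days,session_seen,session_correct,scheduler
u0001,i001,4.275404,1,1,memorize
u0001,i001,10.609937,1,0,memorize
u0001,i001,14.651477,1,1,memorize
u0001,i001,18.156593,1,1,memorize
u0001,i001,22.703344,1,1,memorize
u0001,i002,3.462991,1,1,memorize
u0001,i002,11.372565,1,1,memorize
u0001,i002,27.435295,1,0,memorize
u0001,i003,5.138815,1,1,memorize
u0001,i003,17.046914,1,1,memorize
u0001,i003,26.566546,1,1,memorize
u0001,i004,1.888582,1,1,memorize
u0001,i004,3.512302,1,1,memorize
u0001,i004,5.523222,1,0,memorize
u0001,i004,9.343344,1,1,memorize
u0001,i004,19.217393,1,1,memorize
u0001,i004,25.837978,1,1,memorize
u0002,i001,1.183108,1,1,uniform
u0002,i001,3.084490,1,1,uniform
u0002,i001,4.596133,1,1,uniform
u0002,i001,6.507941,1,1,uniform
u0002,i001,8.463470,1,1,uniform
u0002,i001,9.169302,1,1,uniform
u0002,i001,9.670530,1,1,uniform
u0002,i001,13.848367,1,1,uniform
u0002,i001,15.879110,1,1,uniform
u0002,i001,21.507509,1,1,uniform
u0002,i001,28.734667,1,1,uniform
u0002,i002,1.010089,1,1,uniform
u0002,i002,8.234636,1,1,uniform
u0002,i002,12.754578,1,1,uniform
u0002,i002,15.864313,1,1,uniform
u0002,i002,18.100420,1,1,uniform
u0002,i002,21.498762,1,1,uniform
u0002,i002,28.937395,1,1,uniform
u0002,i002,29.410578,1,1,uniform
u0002,i002,29.643358,1,1,uniform
u0002,i003,0.969951,1,1,uniform
u0002,i003,1.787372,1,1,uniform
u0002,i003,2.673339,1,1,uniform
u0002,i003,4.857846,1,1,uniform
u0002,i003,15.344158,1,0,uniform
u0002,i003,15.849023,1,1,uniform
u0002,i003,19.424822,1,1,uniform
u0002,i003,20.010264,1,1,uniform
u0002,i003,22.061216,1,1,uniform
u0002,i003,26.751241,1,1,uniform
u0002,i003,29.040606,1,1,uniform
u0002,i004,2.813869,1,1,uniform
u0002,i004,10.954973,1,1,uniform
u0002,i004,18.512310,1,1,uniform
u0002,i004,18.558105,1,1,uniform
u0002,i004,20.170233,1,1,uniform
u0002,i004,20.635193,1,1,uniform
u0002,i004,25.038305,1,1,uniform
u0002,i004,26.222104,1,1,uniform
u0002,i004,26.471623,1,1,uniform
u0003,i001,5.980662,1,1,memorize
u0003,i001,15.014156,1,1,memorize
u0003,i001,22.913924,1,1,memorize
u0003,i001,28.294720,1,1,memorize
u0003,i002,7.697246,1,1,memorize
u0003,i002,20.734400,1,1,memorize
u0003,i002,27.247791,1,1,memorize
u0003,i003,6.658973,1,1,memorize
u0003,i003,14.670768,1,0,memorize
u0003,i003,25.208088,1,0,memorize
u0003,i003,27.232788,1,1,memorize
u0003,i004,5.526398,1,0,memorize
u0003,i004,8.656116,1,1,memorize
u0003,i004,12.110561,1,1,memorize
u0003,i004,13.786206,1,1,memorize
u0003,i004,17.746679,1,0,memorize
u0003,i004,21.135049,1,1,memorize
u0004,i001,0.074767,1,1,uniform
u0004,i001,0.165900,1,1,uniform
u0004,i001,9.020457,1,1,uniform
u0004,i001,12.654727,1,0,uniform
u0004,i001,20.769210,1,1,uniform
u0004,i001,20.833108,1,1,uniform
u0004,i001,21.086901,1,1,uniform
u0004,i001,23.813155,1,1,uniform
u0004,i001,23.939115,1,1,uniform
u0004,i001,25.192775,1,1,uniform
u0004,i001,27.972740,1,0,uniform
u0004,i002,2.284806,1,1,uniform
u0004,i002,3.184153,1,1,uniform
u0004,i002,7.080370,1,1,uniform
u0004,i002,11.136251,1,1,uniform
u0004,i002,18.334302,1,1,uniform
u0004,i002,19.747147,1,1,uniform
u0004,i002,27.455439,1,1,uniform
u0004,i003,8.107715,1,1,uniform
u0004,i003,10.938583,1,1,uniform
u0004,i003,12.848530,1,1,uniform
u0004,i003,14.104967,1,1,uniform
u0004,i003,23.687032,1,1,uniform
u0004,i003,24.396814,1,1,uniform
u0004,i003,26.689729,1,1,uniform
u0004,i003,27.221086,1,1,uniform
u0004,i004,3.191083,1,0,uniform
u0004,i004,16.626157,1,0,uniform
u0004,i004,20.700384,1,1,uniform
u0005,i001,4.574397,1,1,memorize
u0005,i001,9.203602,1,1,memorize
u0005,i001,12.186910,1,1,memorize
u0005,i001,23.292016,1,0,memorize
u0005,i002,1.033034,1,1,memorize
u0005,i002,8.329573,1,1,memorize
u0005,i003,4.206202,1,1,memorize
u0005,i003,11.806807,1,1,memorize
u0005,i003,27.064820,1,0,memorize
u0005,i004,1.248297,1,1,memorize
u0005,i004,5.650655,1,1,memorize
u0005,i004,12.774898,1,1,memorize
u0005,i004,21.731828,1,1,memorize
u0005,i004,23.621869,1,1,memorize
u0006,i001,1.975662,1,1,uniform
u0006,i001,5.439419,1,1,uniform
u0006,i001,6.394595,1,1,uniform
u0006,i001,10.770831,1,1,uniform
u0006,i001,20.107737,1,1,uniform
u0006,i001,25.676108,1,1,uniform
u0006,i001,29.567426,1,1,uniform
u0006,i001,29.957964,1,1,uniform
u0006,i002,0.190377,1,1,uniform
u0006,i002,4.913450,1,0,uniform
u0006,i002,14.184512,1,1,uniform
u0006,i002,14.193668,1,1,uniform
u0006,i002,14.973274,1,1,uniform
u0006,i002,19.180150,1,0,uniform
u0006,i002,29.131666,1,1,uniform
u0006,i003,5.120969,1,1,uniform
u0006,i003,12.996601,1,1,uniform
u0006,i003,18.383653,1,1,uniform
u0006,i003,18.664875,1,1,uniform
u0006,i004,5.724880,1,1,uniform
u0006,i004,11.476944,1,0,uniform
u0006,i004,14.778749,1,1,uniform
u0006,i004,15.978550,1,1,uniform
u0006,i004,26.968959,1,1,uniform
u0006,i004,28.669702,1,1,uniform
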