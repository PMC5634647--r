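subject,trial,block,group,start_state,first_choice,second_state,terminal_state,reward,contingency_id,contingency_changed,reward_flip,high_state
1,1,1,1,S1,,S1,S3,0.5389677878008261,0,FALSE,FALSE,S3
1,2,1,1,S0,A2,S2,S4,0.45722862103723227,0,FALSE,FALSE,S3
1,3,1,1,S0,A1,S1,S3,0.54776236650403154,0,FALSE,FALSE,S3
1,4,1,1,S1,,S1,S3,0.67310178945706511,0,FALSE,FALSE,S3
1,5,1,1,S0,A2,S2,S3,0.44337581140293969,1,TRUE,FALSE,S3
1,6,1,1,S1,,S1,S4,0.52754429917511558,1,FALSE,FALSE,S3
1,7,1,1,S1,,S1,S4,0.20334512649422454,1,FALSE,FALSE,S3
1,8,1,1,S1,,S1,S3,0.87841665394723822,0,TRUE,FALSE,S3
1,9,1,1,S1,,S1,S3,0.76859623372974206,0,FALSE,FALSE,S3
1,10,1,1,S0,A2,S2,S4,0.44125728365671762,0,FALSE,TRUE,S4
1,11,1,1,S0,A2,S2,S4,0.55816270071068896,0,FALSE,FALSE,S4
1,12,1,1,S1,,S1,S3,0.27560141455961762,0,FALSE,FALSE,S4
1,13,1,1,S1,,S1,S4,0.31579150157914915,1,TRUE,FALSE,S4
1,14,1,1,S2,,S2,S3,0.50184103877174802,1,FALSE,FALSE,S4
1,15,1,1,S0,A2,S2,S3,0.56116570456951886,1,FALSE,FALSE,S4
1,16,1,1,S1,,S1,S4,0.28867063855171254,1,FALSE,FALSE,S4
1,17,1,1,S1,,S1,S4,0.28268203635748451,1,FALSE,FALSE,S4
1,18,1,1,S0,A2,S2,S4,0.4129536534478031,0,TRUE,FALSE,S4
1,19,1,1,S2,,S2,S4,0.43498564332477735,0,FALSE,FALSE,S4
1,20,1,1,S1,,S1,S3,0.45410588381187761,0,FALSE,TRUE,S3
1,21,2,1,S2,,S2,S4,0.50718576607274268,0,FALSE,FALSE,S3
1,22,2,1,S1,,S1,S3,0.47308927724540961,0,FALSE,FALSE,S3
1,23,2,1,S0,A1,S1,S3,0.72703534388985158,0,FALSE,FALSE,S3
1,24,2,1,S0,A1,S1,S3,0.62334596851270652,0,FALSE,FALSE,S3
1,25,2,1,S2,,S2,S4,0.23964770866582841,0,FALSE,FALSE,S3
1,26,2,1,S0,A1,S1,S3,0.87620238830928421,0,FALSE,FALSE,S3
1,27,2,1,S1,,S1,S3,0.64182168834221121,0,FALSE,FALSE,S3
1,28,2,1,S1,,S1,S4,0.3472027049705444,1,TRUE,FALSE,S3
1,29,2,1,S0,A1,S1,S4,0.34403062042993815,1,FALSE,FALSE,S3
1,30,2,1,S0,A1,S1,S4,0.46739042362536393,1,FALSE,TRUE,S4
1,31,2,1,S0,A1,S1,S4,0.64437892845769018,1,FALSE,FALSE,S4
1,32,2,1,S2,,S2,S3,0.20231960541183203,1,FALSE,FALSE,S4
1,33,2,1,S1,,S1,S4,0.78716750328440876,1,FALSE,FALSE,S4
1,34,2,1,S2,,S2,S3,0.12998819619405111,1,FALSE,FALSE,S4
1,35,2,1,S0,A1,S1,S4,0.60891762100345415,1,FALSE,FALSE,S4
1,36,2,1,S0,A2,S2,S3,0.2606964367097856,1,FALSE,FALSE,S4
1,37,2,1,S0,A1,S1,S4,0.80398449864127286,1,FALSE,FALSE,S4
1,38,2,1,S2,,S2,S4,0.66286605309813085,0,TRUE,FALSE,S4
1,39,2,1,S0,A2,S2,S4,0.79035773345386384,0,FALSE,FALSE,S4
1,40,2,1,S0,A2,S2,S4,0.27725472514041816,0,FALSE,TRUE,S3
1,41,3,1,S1,,S1,S3,0.99567568829651876,0,FALSE,FALSE,S3
1,42,3,1,S2,,S2,S4,0.31395913283574761,0,FALSE,FALSE,S3
1,43,3,1,S2,,S2,S4,0.09071998089435529,0,FALSE,FALSE,S3
1,44,3,1,S0,A1,S1,S3,0.95407310468592721,0,FALSE,FALSE,S3
1,45,3,1,S0,A1,S1,S3,0.79561418378002746,0,FALSE,FALSE,S3
1,46,3,1,S1,,S1,S3,0.79534101941812341,0,FALSE,FALSE,S3
1,47,3,1,S0,A1,S1,S3,0.6149701929240402,0,FALSE,FALSE,S3
1,48,3,1,S0,A2,S2,S4,0.54445886690238998,0,FALSE,FALSE,S3
1,49,3,1,S0,A2,S2,S4,0.587243634890523,0,FALSE,FALSE,S3
1,50,3,1,S2,,S2,S4,0.7074364176702479,0,FALSE,TRUE,S4
1,51,3,1,S2,,S2,S3,0.5383697819973533,1,TRUE,FALSE,S4
1,52,3,1,S2,,S2,S3,0.57279175341363164,1,FALSE,FALSE,S4
1,53,3,1,S2,,S2,S3,0.50291416915143761,1,FALSE,FALSE,S4
1,54,3,1,S1,,S1,S4,0.57499607604213254,1,FALSE,FALSE,S4
1,55,3,1,S2,,S2,S3,0.37091547267182523,1,FALSE,FALSE,S4
1,56,3,1,S1,,S1,S4,0.62384094626755382,1,FALSE,FALSE,S4
1,57,3,1,S1,,S1,S4,0.85378314427446045,1,FALSE,FALSE,S4
1,58,3,1,S0,A2,S2,S3,0.21484733388392219,1,FALSE,FALSE,S4
1,59,3,1,S0,A1,S1,S4,0.56855271289781795,1,FALSE,FALSE,S4
1,60,3,1,S0,A2,S2,S3,0.50454229350233504,1,FALSE,TRUE,S3
2,1,1,2,S2,,S2,S4,0.1028354634055848,0,FALSE,FALSE,S3
2,2,1,2,S1,,S1,S3,0.9719040970020344,0,FALSE,FALSE,S3
2,3,1,2,S1,,S1,S3,0.9259726347027788,0,FALSE,FALSE,S3
2,4,1,2,S0,A1,S1,S3,0.81722444359100654,0,FALSE,FALSE,S3
2,5,1,2,S2,,S2,S4,0.19772317178472432,0,FALSE,FALSE,S3
2,6,1,2,S0,A1,S1,S3,0.67927660160712522,0,FALSE,FALSE,S3
2,7,1,2,S0,A1,S1,S3,0.71967641880352518,0,FALSE,FALSE,S3
2,8,1,2,S2,,S2,S4,0.56254725917730741,0,FALSE,FALSE,S3
2,9,1,2,S1,,S1,S4,0.63302519786357392,1,TRUE,FALSE,S3
2,10,1,2,S1,,S1,S4,0.20957496835434083,1,FALSE,TRUE,S4
2,11,1,2,S0,A1,S1,S4,0.062171165796480576,1,FALSE,FALSE,S4
2,12,1,2,S0,A2,S2,S3,0.79754630021489437,1,FALSE,FALSE,S4
2,13,1,2,S2,,S2,S3,0.60906446211306153,1,FALSE,FALSE,S4
2,14,1,2,S2,,S2,S3,0.52433680713758024,1,FALSE,FALSE,S4
2,15,1,2,S0,A2,S2,S3,0.52284625653698713,1,FALSE,FALSE,S4
2,16,1,2,S0,A2,S2,S3,0.88147303265245114,1,FALSE,FALSE,S4
2,17,1,2,S0,A1,S1,S4,0.46831812798171329,1,FALSE,FALSE,S4
2,18,1,2,S0,A2,S2,S3,0.6786118288959877,1,FALSE,FALSE,S4
2,19,1,2,S1,,S1,S3,0.81063511284490819,0,TRUE,FALSE,S4
2,20,1,2,S0,A1,S1,S3,0.46362817537491985,0,FALSE,TRUE,S3
2,21,2,2,S0,A2,S2,S4,0.53825966953908255,0,FALSE,FALSE,S3
2,22,2,2,S1,,S1,S3,0.35125516735860374,0,FALSE,FALSE,S3
2,23,2,2,S0,A2,S2,S4,0.56559021957449473,0,FALSE,FALSE,S3
2,24,2,2,S1,,S1,S3,0.54466010967569056,0,FALSE,FALSE,S3
2,25,2,2,S2,,S2,S3,0.57555794971001506,1,TRUE,FALSE,S3
2,26,2,2,S0,A2,S2,S3,0.53611992998984725,1,FALSE,FALSE,S3
2,27,2,2,S1,,S1,S4,0.55214468088920987,1,FALSE,FALSE,S3
2,28,2,2,S0,A2,S2,S3,0.35208666609229733,1,FALSE,FALSE,S3
2,29,2,2,S2,,S2,S4,0.6286134377659347,0,TRUE,FALSE,S3
2,30,2,2,S2,,S2,S4,0.5360341448237782,0,FALSE,TRUE,S4
2,31,2,2,S2,,S2,S4,0.37168540663306571,0,FALSE,FALSE,S4
2,32,2,2,S2,,S2,S4,0.44953108641554473,0,FALSE,FALSE,S4
2,33,2,2,S2,,S2,S4,0.26190470586302328,0,FALSE,FALSE,S4
2,34,2,2,S1,,S1,S3,0.76440446003051332,0,FALSE,FALSE,S4
2,35,2,2,S2,,S2,S3,0.55923348392028638,1,TRUE,FALSE,S4
2,36,2,2,S2,,S2,S3,0.59011670787925774,1,FALSE,FALSE,S4
2,37,2,2,S1,,S1,S4,0.54050848669102469,1,FALSE,FALSE,S4
2,38,2,2,S1,,S1,S4,0.63714364904771026,1,FALSE,FALSE,S4
2,39,2,2,S0,A2,S2,S3,0.28760775409284778,1,FALSE,FALSE,S4
2,40,2,2,S0,A2,S2,S3,0.80990057790269632,1,FALSE,TRUE,S3
2,41,3,2,S1,,S1,S4,0.002466079010452038,1,FALSE,FALSE,S3
2,42,3,2,S0,A2,S2,S3,0.8671185265874759,1,FALSE,FALSE,S3
2,43,3,2,S0,A2,S2,S3,0.71613002624027511,1,FALSE,FALSE,S3
2,44,3,2,S0,A2,S2,S3,0.5467831329430346,1,FALSE,FALSE,S3
2,45,3,2,S1,,S1,S4,0.16081716028974236,1,FALSE,FALSE,S3
2,46,3,2,S0,A2,S2,S4,0.15566963353814933,0,TRUE,FALSE,S3
2,47,3,2,S2,,S2,S4,0.054980726553859438,0,FALSE,FALSE,S3
2,48,3,2,S0,A1,S1,S3,0.91133723794196508,0,FALSE,FALSE,S3
2,49,3,2,S0,A1,S1,S3,0.89701666643831779,0,FALSE,FALSE,S3
2,50,3,2,S1,,S1,S3,0.22544483043978658,0,FALSE,TRUE,S4
2,51,3,2,S0,A1,S1,S3,0.27261704745085591,0,FALSE,FALSE,S4
2,52,3,2,S0,A1,S1,S3,0.34391886494923185,0,FALSE,FALSE,S4
2,53,3,2,S0,A1,S1,S3,0.61253640923820685,0,FALSE,FALSE,S4
2,54,3,2,S1,,S1,S3,0.76510882957884707,0,FALSE,FALSE,S4
2,55,3,2,S0,A1,S1,S3,0.78629482530154848,0,FALSE,FALSE,S4
2,56,3,2,S0,A2,S2,S4,0.12752532159166552,0,FALSE,FALSE,S4
2,57,3,2,S1,,S1,S4,0.54874178740931179,1,TRUE,FALSE,S4
2,58,3,2,S0,A2,S2,S3,0.38934240196196912,1,FALSE,FALSE,S4
2,59,3,2,S0,A2,S2,S3,0.39946739145627452,1,FALSE,FALSE,S4
2,60,3,2,S2,,S2,S3,0.51860113887851,1,FALSE,TRUE,S3
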