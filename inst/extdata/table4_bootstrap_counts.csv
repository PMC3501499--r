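group,n_sub,count,lower_bound
Arvicola terrestris,2,801,FALSE
Arvicola terrestris,3,918,FALSE
Arvicola terrestris,4,963,FALSE
Arvicola terrestris,5,984,FALSE
Arvicola terrestris,6,990,TRUE
Arvicola terrestris,7,990,TRUE
Arvicola terrestris,8,990,TRUE
Arvicola terrestris,9,990,TRUE
Myodes glareolus,2,819,FALSE
Myodes glareolus,3,918,FALSE
Myodes glareolus,4,951,FALSE
Myodes glareolus,5,970,FALSE
Myodes glareolus,6,981,FALSE
Myodes glareolus,7,990,TRUE
Myodes glareolus,8,990,TRUE
Myodes glareolus,9,990,TRUE
Microtus agrestis,2,831,FALSE
Microtus agrestis,3,911,FALSE
Microtus agrestis,4,957,FALSE
Microtus agrestis,5,982,FALSE
Microtus agrestis,6,990,FALSE
Microtus agrestis,7,990,TRUE
Microtus agrestis,8,990,TRUE
Microtus agrestis,9,990,TRUE
Microtus arvalis,2,802,FALSE
Microtus arvalis,3,909,FALSE
Microtus arvalis,4,950,FALSE
Microtus arvalis,5,971,FALSE
Microtus arvalis,6,983,FALSE
Microtus arvalis,7,990,TRUE
Microtus arvalis,8,990,TRUE
Microtus arvalis,9,990,TRUE
Apodemus sylvaticus,2,829,FALSE
Apodemus sylvaticus,3,894,FALSE
Apodemus sylvaticus,4,955,FALSE
Apodemus sylvaticus,5,978,FALSE
Apodemus sylvaticus,6,986,FALSE
Apodemus sylvaticus,7,990,TRUE
Apodemus sylvaticus,8,990,TRUE
Apodemus sylvaticus,9,990,TRUE
Mus musculus,2,842,FALSE
Mus musculus,3,897,FALSE
Mus musculus,4,950,FALSE
Mus musculus,5,968,FALSE
Mus musculus,6,982,FALSE
Mus musculus,7,990,TRUE
Mus musculus,8,990,TRUE
Mus musculus,9,990,TRUE
Rattus norvegicus,2,860,FALSE
Rattus norvegicus,3,936,FALSE
Rattus norvegicus,4,969,FALSE
Rattus norvegicus,5,985,FALSE
Rattus norvegicus,6,990,TRUE
Rattus norvegicus,7,990,TRUE
Rattus norvegicus,8,990,TRUE
Rattus norvegicus,9,990,TRUE
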